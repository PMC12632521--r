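# File formats: structured-text model configs and delimited matrix files.
# All numeric output uses 17 significant digits so round-trips are bitwise.

fmt17 <- function(x) formatC(x, digits = 17, format = "g")

#' Read a demographic model from a structured text config
#'
#' The config is YAML with keys `demes` (count or label list) and `epochs`,
#' each epoch a mapping with `t_start`, `t_end` (`"inf"` accepted), exactly
#' one of `adjacency` or `laplacian` (list of rows), and either `gamma` or
#' `Ne` with an optional `ploidy` (default 2, giving `gamma = 1 /
#' (ploidy * Ne)`).
#'
#' @param path config file path.
#' @return A validated [demographic_model()].
#' @export
read_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$epochs)) stop("config has no epochs")
  labels <- NULL
  if (!is.null(cfg$demes) && is.character(cfg$demes)) labels <- cfg$demes
  epochs <- lapply(cfg$epochs, function(e) {
    t_end <- e$t_end
    if (is.character(t_end)) {
      if (tolower(t_end) %in% c("inf", "+inf", "infinity")) t_end <- Inf
      else t_end <- as.numeric(t_end)
    }
    if (!is.null(e$adjacency) && !is.null(e$laplacian)) {
      stop("ambiguous specification: epoch has both adjacency and laplacian")
    }
    if (is.null(e$adjacency) && is.null(e$laplacian)) {
      stop("epoch needs adjacency or laplacian")
    }
    as_mat <- function(rows) do.call(rbind, lapply(rows, as.numeric))
    gamma <- e$gamma
    if (is.null(gamma)) {
      if (is.null(e$Ne)) stop("epoch needs gamma or Ne")
      ploidy <- if (is.null(e$ploidy)) 2 else e$ploidy
      gamma <- 1 / (ploidy * as.numeric(e$Ne))
    }
    if (!is.null(e$adjacency)) {
      epoch_params(e$t_start, t_end, M = as_mat(e$adjacency), gamma = gamma)
    } else {
      epoch_params(e$t_start, t_end, L = as_mat(e$laplacian), gamma = gamma)
    }
  })
  model <- demographic_model(epochs, deme_labels = labels)
  viol <- validate_model(model)
  if (length(viol) > 0) stop(paste(viol, collapse = "; "))
  model
}

#' Write a demographic model config
#'
#' @param model a [demographic_model()].
#' @param path output path.
#' @export
write_model <- function(model, path) {
  cfg <- list(
    demes = if (!is.null(model$deme_labels)) model$deme_labels else model$d,
    epochs = lapply(model$epochs, function(e) {
      list(t_start = e$t_start,
           t_end = if (is.finite(e$t_end)) e$t_end else "inf",
           adjacency = apply(e$M, 1, as.list),
           gamma = as.list(e$gamma))
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

write_matrix_block <- function(B, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(header)) {
    writeLines(sprintf("#%s\t%s", nm, fmt17(header[[nm]])), con)
  }
  utils::write.table(format(B, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

read_matrix_block <- function(path, required = c("x", "y", "d")) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines)
  header <- list()
  for (h in hdr_lines) {
    parts <- strsplit(sub("^#", "", lines[h]), "\t")[[1]]
    header[[parts[1]]] <- as.numeric(parts[2])
  }
  miss <- setdiff(required, names(header))
  if (length(miss) > 0) {
    stop(paste("missing header fields:", paste(miss, collapse = ", ")))
  }
  body <- lines[setdiff(seq_along(lines), hdr_lines)]
  # "NA" marks vacant cells; coercion is intentional
  B <- suppressWarnings(do.call(rbind, lapply(strsplit(body, "\t"),
                                              as.numeric)))
  if (!is.null(header$d) && (nrow(B) != header$d || ncol(B) != header$d)) {
    stop("matrix dimensions do not match the d header field")
  }
  list(B = B, header = header)
}

#' Write / read an expected branch-length matrix
#'
#' Tab-delimited matrix with `#`-prefixed header lines (`x`, `y`, `d`);
#' missing cells are `NA`. Values round-trip bitwise.
#'
#' @param B d x d matrix.
#' @param path file path.
#' @param x,y sampling times (default: taken from attributes of `B`).
#' @return `read_mean_matrix` returns the matrix with attributes `x`, `y`.
#' @export
write_mean_matrix <- function(B, path, x = attr(B, "x"), y = attr(B, "y")) {
  if (is.null(x) || is.null(y)) stop("sampling times x and y required")
  write_matrix_block(as.matrix(B), path,
                     list(x = x, y = y, d = nrow(B)))
}

#' @rdname write_mean_matrix
#' @export
read_mean_matrix <- function(path) {
  out <- read_matrix_block(path, required = c("x", "y", "d"))
  structure(out$B, x = out$header$x, y = out$header$y)
}

#' Write / read an LPSC survival matrix
#'
#' As [write_mean_matrix()] with additional `r` and `mu` header fields.
#'
#' @param rho d x d survival matrix with attributes `r`, `mu`, `x`, `y`.
#' @param path file path.
#' @return `read_survival_matrix` returns the matrix with its attributes.
#' @export
write_survival_matrix <- function(rho, path) {
  hdr <- list(x = attr(rho, "x"), y = attr(rho, "y"), d = nrow(rho),
              r = attr(rho, "r"), mu = attr(rho, "mu"))
  if (any(vapply(hdr, is.null, logical(1)))) {
    stop("survival matrix needs x, y, r, mu attributes")
  }
  write_matrix_block(as.matrix(rho), path, hdr)
}

#' @rdname write_survival_matrix
#' @export
read_survival_matrix <- function(path) {
  out <- read_matrix_block(path, required = c("x", "y", "d", "r", "mu"))
  structure(out$B, x = out$header$x, y = out$header$y,
            r = out$header$r, mu = out$header$mu)
}

#' Write / read a sampled branch-length pdf
#'
#' Long-format tab-delimited file (`i`, `j`, `b`, `density`) with header
#' lines giving the sampling times and grid. Reading returns the long data
#' frame with the header as attributes.
#'
#' @param f a `"branch_pdf"`.
#' @param path file path.
#' @param b evaluation grid (default: 201 points over several means).
#' @return `read_pdf_grid` returns a data frame with attributes `x`, `y`.
#' @export
write_pdf_grid <- function(f, path, b = NULL) {
  if (is.null(b)) {
    lo <- f$segments[[1]]$lo
    b <- seq(lo, lo + 4 * max(pdf_mean(f)), length.out = 201)
  }
  vals <- pdf_evaluate(f, b)
  d <- f$d
  long <- expand.grid(i = 1:d, j = 1:d, k = seq_along(b))
  df <- data.frame(i = long$i, j = long$j, b = b[long$k],
                   density = vals[cbind(long$i, long$j, long$k)])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#x\t%s", fmt17(f$x)), sprintf("#y\t%s", fmt17(f$y)),
               sprintf("#d\t%d", d)), con)
  utils::write.table(format(df, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_pdf_grid
#' @export
read_pdf_grid <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines)
  header <- list()
  for (h in hdr_lines) {
    parts <- strsplit(sub("^#", "", lines[h]), "\t")[[1]]
    header[[parts[1]]] <- as.numeric(parts[2])
  }
  df <- utils::read.table(text = lines[setdiff(seq_along(lines), hdr_lines)],
                          header = TRUE, sep = "\t")
  structure(df, x = header$x, y = header$y, d = header$d)
}

#' Write pairwise samples to TSV
#'
#' @param samples data frame from [simulate_pair()] (optionally with
#'   `lpsc_length`).
#' @param path file path.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
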