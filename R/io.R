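## Delimited-text dataset dialect: columns id, A, delta, T, L, R, Z1..Zp;
## T blank when delta = 0; L and R blank when delta = 1; an infinite upper
## endpoint is written as the literal "Inf"; header required.

#' Read a left-truncated survival dataset from CSV
#'
#' Reads the package's dataset dialect (`id, A, delta, T, L, R, Z1..Zp`) and
#' validates every record; malformed rows are reported with their line number
#' and field. `"Inf"` in column `R` is parsed as an infinite upper endpoint.
#'
#' @param path file path.
#' @return a validated data frame; covariate column names are recorded in
#'   attribute `"covariates"`.
#' @export
read_ltdata <- function(path) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("id", "A", "delta", "T", "L", "R")
  if (length(names(raw)) < 7L || !identical(names(raw)[1:6], need))
    input_error(sprintf(
      "header must start with %s followed by covariate columns",
      paste(need, collapse = ", ")))
  zcols <- names(raw)[-(1:6)]
  num <- function(col, allow_blank, allow_inf = FALSE) {
    x <- trimws(raw[[col]])
    out <- suppressWarnings(as.numeric(x))
    out[x == ""] <- NA_real_
    bad <- x != "" & is.na(out)
    if (!allow_inf) bad <- bad | is.infinite(out)
    if (any(bad))
      input_error(sprintf("line %d, field '%s': malformed value '%s'",
                          which(bad)[1L] + 1L, col, x[which(bad)[1L]]))
    if (!allow_blank && anyNA(out))
      input_error(sprintf("line %d, field '%s': value required",
                          which(is.na(out))[1L] + 1L, col))
    out
  }
  A <- num("A", FALSE)
  delta <- num("delta", FALSE)
  Tm <- num("T", TRUE)
  L <- num("L", TRUE)
  R <- num("R", TRUE, allow_inf = TRUE)
  bad <- delta == 1 & (!is.na(L) | !is.na(R))
  if (any(bad))
    input_error(sprintf("line %d: delta = 1 row carries interval endpoints",
                        which(bad)[1L] + 1L))
  bad <- delta == 0 & !is.na(Tm)
  if (any(bad))
    input_error(sprintf("line %d: delta = 0 row carries an exact event time",
                        which(bad)[1L] + 1L))
  Z <- lapply(zcols, function(cn) num(cn, FALSE))
  out <- data.frame(id = raw$id, A = A, delta = delta, T = Tm, L = L, R = R)
  for (j in seq_along(zcols)) out[[zcols[j]]] <- Z[[j]]
  validate_truncsurv(cbind(entry = A, status = delta, time = Tm,
                           lower = L, upper = R))
  attr(out, "covariates") <- zcols
  out
}

#' Write a left-truncated survival dataset to CSV
#'
#' Inverse of [read_ltdata()]: blanks for inapplicable cells, `"Inf"` for
#' infinite upper endpoints, full double precision so that a write/read round
#' trip reproduces the data exactly.
#'
#' @param data a data frame with columns `id, A, delta, T, L, R, Z...`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ltdata <- function(data, path) {
  need <- c("id", "A", "delta", "T", "L", "R")
  if (!all(need %in% names(data)))
    input_error("data must have columns id, A, delta, T, L, R, Z...")
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "", sprintf("%.17g", x))
    else as.character(x)
  }
  cols <- c(need, setdiff(names(data), need))
  m <- vapply(cols, function(cn) fmt(data[[cn]]), character(nrow(data)))
  if (nrow(data) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, cols))
  lines <- c(paste(cols, collapse = ","),
             apply(m, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}
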