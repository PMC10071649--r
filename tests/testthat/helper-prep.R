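# Build an internal prep structure with an explicit jump grid (for hand
# examples whose grid is stated directly).
manual_prep <- function(grid, A, delta, T = NULL, L = NULL, R = NULL, Z) {
  Z <- as.matrix(Z)
  n <- length(A)
  T <- T %||% rep(NA_real_, n)
  L <- L %||% rep(NA_real_, n)
  R <- R %||% rep(NA_real_, n)
  type <- ifelse(delta == 1, 1L, ifelse(is.finite(R), 2L, 3L))
  iT <- as.integer(ifelse(type == 1L, findInterval(T, grid), 0L))
  iL <- as.integer(ifelse(type != 1L, findInterval(L, grid), 0L))
  iR <- as.integer(ifelse(type == 2L, findInterval(R, grid), 0L))
  list(n = n, p = ncol(Z), Z = Z, grid = grid, K = length(grid),
       type = type, entry = A, status = delta, time = T, lower = L, upper = R,
       iAlt = findInterval(A, grid, left.open = TRUE),
       iAle = findInterval(A, grid),
       iT = iT, iL = iL, iR = iR,
       iRstar = as.integer(ifelse(type == 1L, iT,
                                  ifelse(type == 2L, iR, iL))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a
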