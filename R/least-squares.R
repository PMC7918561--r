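# Shared least-squares solver for the gray-model designs.
#
# Accumulated regressor columns span many orders of magnitude (an AGO GDP
# column reaches ~7e5 while the intercept column is 1), so rank detection on
# the raw matrix is unreliable and explicit normal equations would square an
# already large condition number. Columns are scaled to unit Euclidean norm,
# the system is solved by QR on the scaled matrix, and coefficients are
# mapped back. Returns coefficients plus the raw design condition number;
# genuinely collinear columns raise an error naming them.
gray_ls_solve <- function(B, y, context = "gray model") {
  cn <- colnames(B)
  scale <- sqrt(colSums(B^2))
  if (any(scale == 0))
    stop(sprintf("rank-deficient %s design; collinear columns: %s", context,
                 paste(cn[scale == 0], collapse = ", ")), call. = FALSE)
  Bs <- sweep(B, 2, scale, "/")
  # smooth accumulated series make these designs nearly collinear by
  # construction; only treat collinearity near machine precision as fatal
  qrB <- qr(Bs, tol = 1e-10)
  if (qrB$rank < ncol(B)) {
    drop <- cn[qrB$pivot[(qrB$rank + 1L):ncol(B)]]
    stop(sprintf("rank-deficient %s design; collinear columns: %s", context,
                 paste(drop, collapse = ", ")), call. = FALSE)
  }
  list(coef = stats::setNames(qr.coef(qrB, y) / scale, cn),
       condition = kappa(B, exact = TRUE))
}
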