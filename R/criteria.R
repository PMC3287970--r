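# The three variable-importance criteria (relative loading weights,
# jackknife coefficient q-values, VIP) and the elimination flagging rule.

#' Relative loading-weight criterion
#'
#' Per component a, the relative loading weight of variable j is
#' `|w_aj| / max_j |w_aj|`. The reported value is the maximum over the
#' first `aHat` components, so a variable that is strong in any retained
#' component is protected. Values lie in [0, 1] and at least one variable
#' reaches 1.
#'
#' @param fit a [CpplsFit-class].
#' @param aHat number of retained components (<= fitted components).
#' @return a [CriterionVector-class] of kind `"loading"` (small is bad).
#' @export
criterionLoadingWeights <- function(fit, aHat = fit@nComponents) {
  aHat <- as.integer(aHat)
  if (aHat < 1L || aHat > fit@nComponents)
    stop("aHat must be in 1..nComponents")
  W <- abs(fit@W[, seq_len(aHat), drop = FALSE])
  mx <- apply(W, 2L, max)
  if (any(mx == 0)) stop("degenerate fit: an all-zero loading-weight column")
  r <- apply(sweep(W, 2L, mx, "/"), 1L, max)
  names(r) <- fit@variableIds
  new("CriterionVector", kind = "loading", values = r,
      direction = "small_is_bad")
}

#' Jackknife coefficient q-value criterion
#'
#' Tests each regression coefficient against zero using the variability of
#' the per-cross-validation-segment coefficient estimates. The jackknife
#' variance over m segments is
#' `s_j^2 = (m - 1)/m * sum_seg (beta_j^(-seg) - mean_j)^2`; the statistic
#' `t_j = beta_j / s_j` is referred to a t distribution with m - 1 degrees
#' of freedom (two-sided), and the p-values are converted to q-values by
#' Benjamini-Hochberg. A zero jackknife SE yields p = 0 when the full
#' coefficient is nonzero (perfectly stable, clearly nonzero) and p = 1
#' when it is zero.
#'
#' @param foldBetas list of per-segment coefficient vectors (>= 3 segments)
#'   or the p x m matrix with one column per segment.
#' @param fullBeta coefficient vector of the full-data fit.
#' @return a [CriterionVector-class] of kind `"qvalue"` (large is bad).
#' @export
criterionCoefficientQvalues <- function(foldBetas, fullBeta) {
  B <- if (is.list(foldBetas)) do.call(cbind, foldBetas) else as.matrix(foldBetas)
  m <- ncol(B)
  if (m < 3L) stop("need at least 3 cross-validation segments")
  if (nrow(B) != length(fullBeta))
    stop("fold coefficient vectors and fullBeta differ in length")
  mu <- rowMeans(B)
  s <- sqrt(rowSums((B - mu)^2) * (m - 1) / m)
  tstat <- ifelse(s > 0, fullBeta / s, 0)
  p <- 2 * stats::pt(-abs(tstat), df = m - 1)
  p[s == 0 & fullBeta != 0] <- 0
  p[s == 0 & fullBeta == 0] <- 1
  q <- stats::p.adjust(p, method = "BH")
  names(q) <- names(fullBeta)
  new("CriterionVector", kind = "qvalue", values = q,
      direction = "large_is_bad")
}

#' Variable importance on projections (VIP)
#'
#' VIP of variable j over the first `aHat` components is
#' `sqrt( p * sum_a expl_a (w_aj / ||w_a||)^2 / sum_a expl_a )`
#' with `expl_a = p2_a^2 t_a' t_a`, the response variance explained by
#' component a. The squared values average to 1 across variables
#' (`sum_j v_j^2 = p`), so 1 is the natural reference scale.
#'
#' @inheritParams criterionLoadingWeights
#' @return a [CriterionVector-class] of kind `"vip"` (small is bad).
#' @export
criterionVip <- function(fit, aHat = fit@nComponents) {
  aHat <- as.integer(aHat)
  if (aHat < 1L || aHat > fit@nComponents)
    stop("aHat must be in 1..nComponents")
  keep <- seq_len(aHat)
  tt <- colSums(fit@scores[, keep, drop = FALSE]^2)
  expl <- fit@p2[keep]^2 * tt
  if (sum(expl) <= 0)
    stop("degenerate fit: no component explains response variance")
  W <- fit@W[, keep, drop = FALSE]
  Wn2 <- sweep(W^2, 2L, colSums(W^2), "/")
  p <- nrow(W)
  v <- sqrt(p * as.vector(Wn2 %*% expl) / sum(expl))
  names(v) <- fit@variableIds
  new("CriterionVector", kind = "vip", values = v,
      direction = "small_is_bad")
}

#' Flag variables for elimination against a cutoff
#'
#' For the loading and VIP criteria a variable is flagged when its value is
#' below `u`; for the q-value criterion when it is above `u`.
#'
#' @param criterion a [CriterionVector-class].
#' @param u cutoff (in [0, 1] for loading/qvalue, [0, Inf) for VIP).
#' @return integer indices of the flagged variables (possibly empty).
#' @examples
#' cv <- new("CriterionVector", kind = "vip", values = c(0.2, 1.5, 12),
#'           direction = "small_is_bad")
#' flagForElimination(cv, 10)
#' @export
flagForElimination <- function(criterion, u) {
  stopifnot(is(criterion, "CriterionVector"))
  hi <- if (criterion@kind == "vip") Inf else 1
  if (u < 0 || u > hi) stop("cutoff u outside the criterion's valid range")
  if (criterion@direction == "large_is_bad") which(criterion@values > u)
  else which(criterion@values < u)
}

# Order flagged variables from most to least extreme, breaking ties by
# ascending variable index for determinism.
.extremeOrder <- function(criterion, flagged) {
  v <- criterion@values[flagged]
  if (criterion@direction == "large_is_bad")
    flagged[order(-v, flagged)]
  else
    flagged[order(v, flagged)]
}
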