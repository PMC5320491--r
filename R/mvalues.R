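#' Beta/M-value transforms for DNA methylation
#'
#' The M value is the logit2 transform of the methylation fraction
#' (beta value): `M = log2(beta / (1 - beta))`. It is the modelling scale for
#' methylation; beta is the reporting scale. The two functions are exact
#' inverses on (0, 1).
#'
#' @param beta methylation fractions, strictly inside (0, 1).
#' @return `beta_to_m`: M values (real); `m_to_beta`: beta fractions in (0, 1).
#' @examples
#' beta_to_m(0.5) # 0
#' beta_to_m(0.8) # 2
#' m_to_beta(beta_to_m(0.123))
#' @export
beta_to_m <- function(beta) {
  if (!is.numeric(beta)) stopf("beta must be numeric")
  if (any(!is.finite(beta)) || any(beta <= 0) || any(beta >= 1))
    stopf("beta values must lie strictly in (0, 1)")
  log2(beta / (1 - beta))
}

#' @param m M values (any real).
#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  if (!is.numeric(m)) stopf("m must be numeric")
  if (any(!is.finite(m))) stopf("m values must be finite")
  1 / (1 + 2^(-m))
}
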