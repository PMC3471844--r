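#' Copy-number state labels
#'
#' The five copy-number states used throughout the package, in a fixed
#' order suitable for factor levels.
#'
#' @details States partition the non-negative copy-number axis:
#' amplification (CN > 3), neutral (1.5 <= CN <= 3), hemizygous deletion
#' (0.8 <= CN < 1.5), homozygous deletion (CN < 0.5), and
#' `deletion_unclassified` for the unnamed band (0.5 <= CN < 0.8) which
#' still counts as deleted under the operative CN < 1.5 rule.
#'
#' @return Character vector of the five state names.
#' @export
cn_states <- function() {
  c("amplification", "neutral", "hemizygous_deletion",
    "homozygous_deletion", "deletion_unclassified")
}

#' Classify copy-number values into CNV states
#'
#' Assigns each linear-scale copy-number estimate (diploid = 2) to one of
#' five states: values strictly above 3 are amplifications; values strictly
#' below 1.5 are deletions, subdivided into homozygous (CN < 0.5),
#' hemizygous (0.8 <= CN < 1.5) and an unclassified band (0.5 <= CN < 0.8);
#' everything in \[1.5, 3\] is neutral.
#'
#' @param cn Numeric vector of copy-number estimates. Must be finite and
#'   non-negative.
#' @return Character vector of states (see [cn_states()]).
#' @seealso [is_deleted()], [is_amplified()]
#' @examples
#' classify_cn(c(3.671, 0.9596, 2.0, 0.3))
#' @export
classify_cn <- function(cn) {
  if (!is.numeric(cn)) stop("'cn' must be numeric")
  if (any(!is.finite(cn)) || any(cn < 0)) {
    stop("copy-number values must be finite and non-negative")
  }
  state <- rep("neutral", length(cn))
  state[cn > 3] <- "amplification"
  state[cn < 0.5] <- "homozygous_deletion"
  state[cn >= 0.5 & cn < 0.8] <- "deletion_unclassified"
  state[cn >= 0.8 & cn < 1.5] <- "hemizygous_deletion"
  state
}

#' Deletion and amplification predicates
#'
#' `is_deleted()` is TRUE for CN strictly below 1.5 (any of the three
#' deletion states); `is_amplified()` for CN strictly above 3. The two are
#' mutually exclusive.
#'
#' @param cn Numeric vector of copy-number estimates (finite, >= 0).
#' @return Logical vector.
#' @export
is_deleted <- function(cn) {
  if (any(!is.finite(cn)) || any(cn < 0)) {
    stop("copy-number values must be finite and non-negative")
  }
  cn < 1.5
}

#' @rdname is_deleted
#' @export
is_amplified <- function(cn) {
  if (any(!is.finite(cn)) || any(cn < 0)) {
    stop("copy-number values must be finite and non-negative")
  }
  cn > 3
}
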