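# Reference dataset bookkeeping: the published multi-center pressure-injury
# cohort behind the method (counts only; no images ship with the package).

#' Per-source image counts of the reference pressure-injury cohort
#'
#' The reference dataset pools three in-house clinical sources and one
#' public dataset (PIID).  After excluding unstageable, suspected
#' deep-tissue and mucosal injuries, the included counts sum to the
#' published total of 1,519 images.
#'
#' @return A tibble with columns `source`, `collected`, `included`.
#' @examples
#' sum(pi_inclusion_counts()$included)  # 1519
#' @export
pi_inclusion_counts <- function() {
  tibble::tibble(
    source = c("Wuhan University Renmin Hospital",
               "Union Hospital Tongji Medical College",
               "Zhongshan Hospital Xiamen University",
               "PIID (public)"),
    collected = c(363L, 80L, 76L, 1091L),
    included = c(291L, 72L, 65L, 1091L)
  )
}

#' Published per-stage image counts and split sizes
#'
#' Per-stage totals of the reference cohort with the train/validation
#' sizes produced by the seed-fixed 8:2 stratified split under the
#' flooring rule (validation per class = `floor(0.2 * n)`).
#'
#' @return A tibble with columns `stage`, `train`, `validation`, `total`.
#' @export
pi_stage_counts <- function() {
  tibble::tibble(
    stage = paste0("stage", 1:4),
    train = c(308L, 419L, 255L, 235L),
    validation = c(77L, 104L, 63L, 58L),
    total = c(385L, 523L, 318L, 293L)
  )
}

#' Dataset-level channel normalization constants
#'
#' Mean and standard deviation RGB triples of the reference cohort, used
#' to normalize inputs during preprocessing.  Recompute for a new dataset
#' with [dataset_stats()].
#'
#' @return A list with numeric triples `mean` and `std`.
#' @export
pi_norm_stats <- function() {
  list(mean = c(0.537, 0.424, 0.393), std = c(0.523, 0.416, 0.376))
}
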