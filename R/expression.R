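# Expression normalisation, Shannon-entropy tissue specificity,
# expressed-organ counts, and deterministic feature clustering.

#' Transcripts-per-million normalisation
#'
#' `rate = count / length`; each sample column is scaled so its TPM sum
#' is exactly 1e6.
#'
#' @param counts Tibble in long format with columns `feature_id`,
#'   `sample`, `count`, or a numeric matrix (features x samples).
#' @param effective_lengths Named numeric vector of per-feature lengths
#'   (> 0), or a tibble `feature_id`, `length`.
#' @return Same shape as the input with a `tpm` column (long input) or a
#'   TPM matrix.
#' @export
tpm <- function(counts, effective_lengths) {
  if (is.data.frame(effective_lengths)) {
    effective_lengths <- setNames(effective_lengths$length,
                                  effective_lengths$feature_id)
  }
  if (any(effective_lengths <= 0)) stop("feature with non-positive length")
  if (is.matrix(counts)) {
    len <- effective_lengths[rownames(counts)]
    if (any(is.na(len))) stop("length missing for some features")
    rate <- counts / len
    return(sweep(rate, 2, colSums(rate), "/") * 1e6)
  }
  stopifnot(all(c("feature_id", "sample", "count") %in% names(counts)))
  len <- effective_lengths[counts$feature_id]
  if (any(is.na(len))) stop("length missing for some features")
  counts %>%
    mutate(rate = .data$count / .env$len) %>%
    group_by(.data$sample) %>%
    mutate(tpm = .data$rate / sum(.data$rate) * 1e6) %>%
    ungroup() %>%
    select(-"rate")
}

#' Shannon-entropy tissue specificity
#'
#' For an organ-level mean-TPM profile, `P_n = TPM_n / sum(TPM)` and
#' `H = -sum(P_n * log2(P_n))` with `0 * log(0) = 0`. `H` is 0 when the
#' feature is expressed in a single organ and `log2(m)` when expressed
#' uniformly over all `m` organs; an all-zero profile has undefined
#' entropy (`NA`).
#'
#' @param profiles Tibble `feature_id`, `organ`, `tpm` (organ-level
#'   means), or a numeric vector for a single feature.
#' @return Tibble `feature_id`, `entropy`, `n_organs`,
#'   `n_expressed_organs`; or a single number for vector input.
#' @export
shannon_entropy <- function(profiles) {
  h <- function(x) {
    if (any(x < 0)) stop("negative expression values")
    s <- sum(x)
    if (s == 0) return(NA_real_)
    p <- x / s
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  if (is.numeric(profiles)) return(h(profiles))
  stopifnot(all(c("feature_id", "organ", "tpm") %in% names(profiles)))
  profiles %>%
    group_by(.data$feature_id) %>%
    summarise(entropy = h(.data$tpm), n_organs = n(),
              n_expressed_organs = sum(.data$tpm > 0), .groups = "drop")
}

#' Count organs in which a feature is expressed
#'
#' @param profiles As in [shannon_entropy()], or a numeric vector.
#' @param threshold Expression cutoff; an organ counts when its mean TPM
#'   is strictly greater than `threshold` (default 0).
#' @return Tibble `feature_id`, `n_expressed_organs`, or an integer for
#'   vector input.
#' @export
expressed_organ_count <- function(profiles, threshold = 0) {
  if (is.numeric(profiles)) return(sum(profiles > threshold))
  profiles %>%
    group_by(.data$feature_id) %>%
    summarise(n_expressed_organs = sum(.data$tpm > threshold),
              .groups = "drop")
}

#' Organ-level mean TPM profiles from a sample-level table
#'
#' @param expression Long tibble `feature_id`, `sample`, `tpm` plus a
#'   sample table mapping `sample` to `organ`.
#' @param samples Tibble `sample`, `organ`.
#' @return Tibble `feature_id`, `organ`, `tpm` (replicate means).
#' @export
organ_profiles <- function(expression, samples) {
  expression %>%
    inner_join(samples[c("sample", "organ")], by = "sample") %>%
    group_by(.data$feature_id, .data$organ) %>%
    summarise(tpm = mean(.data$tpm), .groups = "drop")
}

#' Cluster expression profiles into k groups
#'
#' Rows are scaled to zero mean and unit variance, then clustered by
#' Ward-linkage hierarchical clustering on Euclidean distances and cut
#' at `k`: fully deterministic. Rows with zero variance are scaled to
#' zeros (flagged degenerate rather than erroring).
#'
#' @param mat Numeric matrix (features x conditions) with rownames.
#' @param k Number of clusters, `2 <= k <= nrow(mat)`.
#' @return Tibble `feature_id`, `cluster` (integer labels 1..k).
#' @export
cluster_features <- function(mat, k) {
  stopifnot(is.matrix(mat), k >= 2)
  if (k > nrow(mat)) stop("k exceeds the number of features")
  sds <- apply(mat, 1, sd)
  scaled <- t(scale(t(mat)))
  scaled[sds == 0, ] <- 0
  hc <- hclust(dist(scaled), method = "ward.D2")
  cl <- cutree(hc, k = k)
  tibble::tibble(feature_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
                 cluster = as.integer(cl))
}
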