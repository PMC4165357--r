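# Chance tag collisions: the birthday problem for SMTs.
#
# Two template molecules of the same target may independently receive the
# same tag, and the resulting "duplicate" is then a chance collision, not a
# PCR copy. Two complementary quantifications are provided: a Poisson model
# of per-sequence usage counts across the whole experiment, and an
# occupancy resampling estimator of the within-target collision fraction
# under any tag-usage distribution (uniform or empirically biased).

#' Poisson model of SMT sequence usage
#'
#' With `n_draws` tags drawn independently and uniformly from the `K = 4^L`
#' possible sequences, the usage count of each sequence is approximately
#' Poisson with rate `n_draws / K`.
#'
#' @param L tag length in bases.
#' @param n_draws number of independent tag observations (e.g. one instance
#'   of each tag per target per sample).
#' @return object of class `collision_model` with fields `L`, `K`,
#'   `n_draws`, `lam`.
#' @export
collision_model <- function(L, n_draws) {
  L <- as.integer(L)
  stopifnot(L >= 1L, n_draws >= 0)
  K <- 4^L
  structure(list(L = L, K = K, n_draws = as.double(n_draws), lam = n_draws / K),
            class = "collision_model")
}

#' @export
print.collision_model <- function(x, ...) {
  cat(sprintf("Poisson SMT usage model: L = %d (K = %s sequences), %s draws, rate %.4g\n",
              x$L, format(x$K, big.mark = ","),
              format(x$n_draws, big.mark = ","), x$lam))
  invisible(x)
}

#' Expected number of distinct tag sequences observed
#'
#' `K * (1 - P(Pois(lam) = 0)) = K * (1 - exp(-lam))`. Strictly increasing
#' in `n_draws` and bounded by `min(n_draws, K)`.
#'
#' @param model a [collision_model()].
#' @export
expected_distinct <- function(model) {
  stopifnot(inherits(model, "collision_model"))
  model$K * -expm1(-model$lam)
}

#' Expected number of tag sequences observed at least k times
#'
#' `K * P(Pois(lam) >= k)`, with the tail computed as a survival function in
#' log space so that `K` times a tiny tail probability does not underflow.
#'
#' @param model a [collision_model()].
#' @param k minimal usage count (>= 1).
#' @export
expected_count_at_least <- function(model, k) {
  stopifnot(inherits(model, "collision_model"), k >= 1)
  exp(log(model$K) +
        ppois(k - 1, model$lam, lower.tail = FALSE, log.p = TRUE))
}

#' Expected number of tag sequences observed exactly k times, k = 1..k_max
#'
#' @param model a [collision_model()].
#' @param k_max largest usage count tabulated.
#' @return data.frame with columns `k`, `expected` (`K * P(Pois(lam) = k)`).
#' @export
expected_sequence_count_distribution <- function(model, k_max) {
  stopifnot(inherits(model, "collision_model"), k_max >= 1)
  k <- seq_len(k_max)
  data.frame(k = k, expected = model$K * dpois(k, model$lam))
}

#' Summary statistics of SMT sequence usage
#'
#' Convenience wrapper combining the Poisson expectations with the simple
#' bookkeeping quantities of a tag-usage analysis: the theoretical maximum
#' multiplicity of one sequence (`n_samples * n_targets`, one instance per
#' target per sample) and the mean usage per observed sequence, both under
#' the model (`n_draws / expected_distinct`) and, when an observed distinct
#' count is supplied, as observed (`n_draws / n_observed_distinct`).
#'
#' @param model a [collision_model()].
#' @param n_samples,n_targets experiment dimensions (optional).
#' @param n_observed_distinct observed number of distinct sequences
#'   (optional).
#' @return list with fields `expected_distinct`, `mean_usage_model`,
#'   `max_multiplicity`, `mean_usage_observed`.
#' @export
smt_usage_summary <- function(model, n_samples = NULL, n_targets = NULL,
                              n_observed_distinct = NULL) {
  ed <- expected_distinct(model)
  list(expected_distinct = ed,
       mean_usage_model = if (ed > 0) model$n_draws / ed else NA_real_,
       max_multiplicity = if (!is.null(n_samples) && !is.null(n_targets))
         n_samples * n_targets else NA_real_,
       mean_usage_observed = if (!is.null(n_observed_distinct))
         model$n_draws / n_observed_distinct else NA_real_)
}

#' Empirical SMT usage distribution
#'
#' Counts each tag once per target per sample (duplicates within a target
#' reflect PCR, usage across targets and samples does not), yielding the
#' usage distribution the resampling collision estimator draws from.
#'
#' @param annotations data.frame with columns `sample_id`, `target_id`,
#'   `smt` (e.g. the output of [mark_duplicates()]).
#' @return named integer vector of counts per tag sequence, class
#'   `smt_distribution`, with the tag length in attribute `L`.
#' @export
smt_frequency_distribution <- function(annotations) {
  if (!"sample_id" %in% names(annotations)) annotations$sample_id <- "S1"
  key <- paste(annotations$sample_id, annotations$target_id, annotations$smt,
               sep = "\r")
  smt <- annotations$smt[!duplicated(key)]
  tab <- table(smt)
  out <- setNames(as.integer(tab), names(tab))
  attr(out, "L") <- nchar(names(out)[1L])
  class(out) <- "smt_distribution"
  out
}

#' Aggregate a tag usage distribution to its first new_L bases
#'
#' Total counts are preserved; used to ask how an 8-base prefix of a
#' 12-base tag would have performed.
#'
#' @param dist an `smt_distribution` (named counts).
#' @param new_L new (shorter) tag length.
#' @export
truncate_to_prefix <- function(dist, new_L) {
  new_L <- as.integer(new_L)
  if (new_L <= 0L) stop("new_L must be positive", call. = FALSE)
  L <- attr(dist, "L")
  if (!is.null(L) && new_L >= L) stop("new_L must be shorter than the current tag length",
                                      call. = FALSE)
  pre <- substr(names(dist), 1L, new_L)
  agg <- rowsum(as.integer(dist), pre)
  out <- setNames(as.integer(agg[, 1L]), rownames(agg))
  attr(out, "L") <- new_L
  class(out) <- "smt_distribution"
  out
}

#' Analytic within-target collision fraction under uniform tag usage
#'
#' For `depth` i.i.d. uniform draws from `K = 4^L` tags, the expected number
#' of distinct tags is `K * (1 - (1 - 1/K)^depth)`; the rest of the draws
#' repeat an already-drawn tag. Returns that expected repeated fraction,
#' `1 - K * (1 - (1 - 1/K)^depth) / depth`.
#'
#' @param L tag length in bases.
#' @param depth reads (tag draws) per target.
#' @export
collision_fraction_uniform <- function(L, depth) {
  stopifnot(depth >= 1)
  K <- 4^L
  1 - K * -expm1(depth * log1p(-1 / K)) / depth
}

#' Within-target chance-collision fraction by resampling
#'
#' For each of `n_targets` targets, draws `depth` tags i.i.d. from the
#' given usage distribution (probability proportional to count) or, when
#' `dist` is `NULL`, uniformly from all `4^L` sequences. A draw whose tag
#' has already been drawn for the same target is a chance collision.
#' Per-target RNG streams are derived deterministically from `seed`.
#'
#' @param dist an `smt_distribution`, or `NULL` for the uniform reference.
#' @param L tag length (required when `dist` is `NULL`).
#' @param depth reads per target.
#' @param n_targets number of targets resampled.
#' @param seed RNG seed.
#' @return total collisions / total draws.
#' @export
collision_fraction_by_resampling <- function(dist = NULL, L = NULL, depth,
                                             n_targets, seed) {
  stopifnot(depth >= 1, n_targets >= 1)
  if (is.null(dist)) {
    stopifnot(!is.null(L))
    K <- 4^as.integer(L)
    draw <- function() sample.int(K, depth, replace = TRUE)
  } else {
    p <- as.numeric(dist) / sum(dist)
    nd <- length(p)
    draw <- function() sample.int(nd, depth, replace = TRUE, prob = p)
  }
  collisions <- 0
  for (t in seq_len(n_targets)) {
    set.seed(derive_seed(seed, t))
    x <- draw()
    collisions <- collisions + depth - length(unique(x))
  }
  collisions / (depth * n_targets)
}
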