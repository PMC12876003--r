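#' Generate a satisfaction survey with exact target means
#'
#' Draws integer ratings from a latent normal at each criterion's target
#' mean, rounds and clips to the rating scale, then greedily adjusts ratings
#' (single +/-1 steps on randomly chosen respondents, within scale) until
#' each criterion's mean matches its target to +/-0.005. The achievable mean
#' granularity is 1/n, so targets printed at 3 decimals for n = 140 and at 1
#' decimal for n = 10 are met by construction; an unattainable target (outside
#' the scale) errors.
#'
#' @param framework a `criteria_framework`.
#' @param n number of respondents.
#' @param target_means named per-criterion target means (defaults to 6 for
#'   every criterion).
#' @param sd latent dispersion of ratings (default 1.5 scale points).
#' @param seed integer seed; generation is deterministic given the seed.
#' @param missing_rate fraction of ratings blanked to NA after mean matching
#'   (default 0), for exercising respondent-validity filters.
#' @param scale rating scale bounds (default c(1, 10)).
#' @param panel_label label stored on the result attribute.
#' @return data.frame with columns `respondent_id`, `criterion_code`,
#'   `rating`.
#' @export
gen_satisfaction_survey <- function(framework, n, target_means = NULL,
                                    sd = 1.5, seed = 1, missing_rate = 0,
                                    scale = c(1, 10),
                                    panel_label = "resident") {
  codes <- framework$criteria$code
  if (is.null(target_means)) target_means <- stats::setNames(rep(6, length(codes)), codes)
  target_means <- target_means[codes]
  stopifnot(!anyNA(target_means), missing_rate >= 0, missing_rate < 1, sd >= 0)
  if (any(target_means < scale[1] | target_means > scale[2])) {
    stop(errorCondition("target mean outside the rating scale",
                        class = c("danpv_scale_error", "danpv_error")))
  }
  set.seed(seed)
  ratings <- matrix(0L, nrow = n, ncol = length(codes),
                    dimnames = list(NULL, codes))
  for (j in seq_along(codes)) {
    x <- round(stats::rnorm(n, target_means[j], sd))
    x <- pmin(scale[2], pmax(scale[1], x))
    target_sum <- round(target_means[j] * n)
    # greedy +/-1 adjustments toward the target sum
    while (sum(x) != target_sum) {
      step <- sign(target_sum - sum(x))
      movable <- if (step > 0) which(x < scale[2]) else which(x > scale[1])
      i <- movable[sample.int(length(movable), 1)]
      x[i] <- x[i] + step
    }
    ratings[, j] <- as.integer(x)
  }
  out <- data.frame(
    respondent_id = rep(sprintf("R%03d", seq_len(n)), times = length(codes)),
    criterion_code = rep(codes, each = n),
    rating = as.vector(ratings),
    stringsAsFactors = FALSE)
  if (missing_rate > 0) {
    drop <- stats::runif(nrow(out)) < missing_rate
    out$rating[drop] <- NA_integer_
  }
  attr(out, "panel_label") <- panel_label
  out
}

#' Build a structured base direct-influence matrix
#'
#' Helper for [gen_dematel_panel()]: a base 0-4 integer matrix whose induced
#' dimension influence follows a prescribed qualitative pattern. Each entry
#' from criterion i to criterion j is `round((out[d(i)] + receive[d(j)]) / 2)`
#' clipped to the 0-4 scale, so dimensions with high `out` become net causes
#' and dimensions with high `receive` become net receivers.
#'
#' @param framework a `criteria_framework`.
#' @param out named per-dimension outgoing strength on the 0-4 scale
#'   (default 2 everywhere).
#' @param receive named per-dimension receptivity on the 0-4 scale
#'   (default 2 everywhere).
#' @return an n x n integer matrix with zero diagonal.
#' @export
dematel_structure <- function(framework, out = NULL, receive = NULL) {
  dcodes <- framework$dimensions$code
  if (is.null(out)) out <- stats::setNames(rep(2, length(dcodes)), dcodes)
  if (is.null(receive)) receive <- stats::setNames(rep(2, length(dcodes)), dcodes)
  dim_of <- criterion_dimension(framework)
  base <- outer(unname(out[dim_of]), unname(receive[dim_of]),
                function(a, b) round((a + b) / 2))
  base <- pmin(pmax(base, 0), 4)
  diag(base) <- 0
  codes <- framework$criteria$code
  dimnames(base) <- list(codes, codes)
  base
}

#' Generate a panel of DEMATEL expert questionnaires
#'
#' Each expert's matrix is the base matrix plus independent integer noise
#' (uniform on -noise..noise per off-diagonal cell), clipped to the 0-4
#' questionnaire scale, with a zero diagonal. With `noise = 0` all experts
#' coincide and the test-retest difference of two such panels is zero.
#'
#' @param framework a `criteria_framework`.
#' @param k number of experts (default 9).
#' @param base base matrix (default [dematel_structure()] with flat levels).
#' @param noise integer noise half-width (default 1).
#' @param seed integer seed.
#' @return list of k integer matrices.
#' @export
gen_dematel_panel <- function(framework, k = 9, base = NULL, noise = 1,
                              seed = 1) {
  stopifnot(k >= 1, noise >= 0)
  if (is.null(base)) base <- dematel_structure(framework)
  set.seed(seed)
  n <- nrow(base)
  lapply(seq_len(k), function(e) {
    eps <- matrix(sample(seq(-noise, noise), n * n, replace = TRUE), n, n)
    m <- pmin(pmax(base + eps, 0), 4)
    diag(m) <- 0
    dimnames(m) <- dimnames(base)
    m
  })
}

#' Generate a Fuzzy Delphi questionnaire panel
#'
#' Each expert rates every criterion with a conservative and an optimistic
#' score drawn around per-criterion targets, clipped so that conservative <
#' optimistic holds for valid experts. Criteria listed in `low_criteria` are
#' given depressed targets so their consensus falls below the screening
#' threshold. `n_invalid` additional experts are injected with a violation
#' (an inconsistent pair or a missing item) so that panel validation rejects
#' exactly those questionnaires.
#'
#' @param framework a `criteria_framework`.
#' @param k number of valid experts (default 23).
#' @param cons_target,opt_target conservative / optimistic rating targets
#'   (defaults 5 and 8).
#' @param sd latent rating dispersion (default 1).
#' @param low_criteria criterion codes to target below the threshold.
#' @param n_invalid number of invalid experts to inject (default 0).
#' @param seed integer seed.
#' @return data.frame with columns `expert_id`, `criterion_code`,
#'   `conservative`, `optimistic`.
#' @export
gen_fdm_panel <- function(framework, k = 23, cons_target = 5, opt_target = 8,
                          sd = 1, low_criteria = NULL, n_invalid = 0,
                          seed = 1) {
  stopifnot(k >= 1, n_invalid >= 0)
  set.seed(seed)
  codes <- framework$criteria$code
  gen_expert <- function(id) {
    ct <- rep(cons_target, length(codes))
    ot <- rep(opt_target, length(codes))
    low <- codes %in% low_criteria
    ct[low] <- 1.5
    ot[low] <- 3
    cons <- pmin(9, pmax(1, round(stats::rnorm(length(codes), ct, sd))))
    opt <- pmin(10, pmax(cons + 1, round(stats::rnorm(length(codes), ot, sd))))
    data.frame(expert_id = id, criterion_code = codes,
               conservative = cons, optimistic = opt,
               stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, lapply(sprintf("E%02d", seq_len(k)), gen_expert))
  if (n_invalid > 0) {
    bad <- do.call(rbind, lapply(seq_len(n_invalid), function(i) {
      b <- gen_expert(sprintf("X%02d", i))
      if (i %% 2 == 1) {
        b$conservative[1] <- b$optimistic[1] + 1  # inconsistent pair
        b$conservative[1] <- min(b$conservative[1], 10)
        b$optimistic[1] <- min(b$optimistic[1], b$conservative[1])
      } else {
        b <- b[-1, ]  # missing item
      }
      b
    }))
    panel <- rbind(panel, bad)
  }
  rownames(panel) <- NULL
  panel
}
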