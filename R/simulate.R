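# Synthetic cohorts: seeded stand-in for the hardware random-number generator
# behind the trial randomization, with the two-bit XOR assignment scheme.

#' Five-lab cohort structure of the multi-lab replication
#'
#' Per-lab sample sizes of the five participating labs, in descending size
#' order, totalling 2,004 participants.
#'
#' @return Tibble with columns `label` and `size`.
#' @examples
#' replication_labs()
#' sum(replication_labs()$size)   # 2004
#' @export
replication_labs <- function() {
  tibble(label = c("Germany", "Italy", "Russia", "France", "Sweden"),
         size = c(1413L, 235L, 154L, 103L, 99L))
}

#' Published per-lab summary table of the replication
#'
#' The printed per-lab descriptive summaries (sample size, mean
#' negative-picture count out of 60 trials, standard deviation) together with
#' the reported one-sided Bayes factors, usable as input to
#' [lab_bayes_factors()] and [meta_random_effects()].
#'
#' @return Tibble with columns `label`, `n`, `mean`, `sd`, `bf10_reported`.
#' @examples
#' replication_lab_table()
#' @export
replication_lab_table <- function() {
  tibble(label = c("Germany", "Italy", "Russia", "France", "Sweden"),
         n = c(1413L, 235L, 154L, 103L, 99L),
         mean = c(30.00, 30.12, 29.49, 29.52, 30.20),
         sd = c(3.88, 4.10, 3.83, 4.27, 3.80),
         bf10_reported = c(0.20, 0.31, 1.93, 1.19, 0.40))
}

.check_p <- function(p_negative) {
  if (!is.numeric(p_negative) || length(p_negative) != 1L ||
      !is.finite(p_negative) || p_negative <= 0 || p_negative >= 1) {
    abort("`p_negative` must be a single probability strictly inside (0, 1).")
  }
}

#' Simulate trial-level records for one participant
#'
#' Emulates the trial randomization: each trial carries a pre-stored bit and a
#' live bit drawn at response time, and the picture valence is determined by
#' their XOR (`outcome_bit = prestored_bit XOR live_bit`; 1 maps to a negative
#' picture, 0 to a neutral one).  Under `p_negative = 0.5` both bits are
#' independent fair bits.  An avoidance effect is injected by biasing the
#' live bit so that the XOR outcome is Bernoulli(`p_negative`) while the
#' pre-stored bit stays fair and the XOR identity is preserved.
#'
#' @param n_trials Number of trials (>= 1, default 60).
#' @param p_negative Per-trial probability of a negative-picture outcome.
#' @param participant_id Identifier copied into every record.
#' @return Tibble with columns `participant_id`, `trial_index`,
#'   `prestored_bit`, `live_bit`, `outcome_bit`, `valence`.
#' @examples
#' tr <- simulate_trials(n_trials = 5, participant_id = "P1")
#' all(tr$outcome_bit == bitwXor(tr$prestored_bit, tr$live_bit))
#' @export
simulate_trials <- function(n_trials = 60, p_negative = 0.5, participant_id = "P1") {
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) abort("`n_trials` must be an integer >= 1.")
  .check_p(p_negative)
  prestored <- as.integer(runif(n_trials) < 0.5)
  outcome <- as.integer(runif(n_trials) < p_negative)
  live <- bitwXor(prestored, outcome)
  tibble(participant_id = participant_id,
         trial_index = seq_len(n_trials),
         prestored_bit = prestored,
         live_bit = live,
         outcome_bit = outcome,
         valence = ifelse(outcome == 1L, "negative", "neutral"))
}

#' Simulate one participant record
#'
#' Draws `n_trials` trial outcomes via the XOR scheme of [simulate_trials()]
#' and aggregates them into the participant's negative-picture count, which is
#' Binomial(`n_trials`, `p_negative`) by construction.
#'
#' @param lab_label Lab label for the record.
#' @param collection_order Position in the cohort-wide collection order.
#' @inheritParams simulate_trials
#' @return One-row tibble with columns `participant_id`, `lab`,
#'   `collection_order`, `n_trials`, `negative_count`.
#' @export
simulate_participant <- function(lab_label, collection_order, n_trials = 60,
                                 p_negative = 0.5,
                                 participant_id = sprintf("P%05d", collection_order)) {
  trials <- simulate_trials(n_trials, p_negative, participant_id)
  tibble(participant_id = participant_id,
         lab = lab_label,
         collection_order = as.integer(collection_order),
         n_trials = as.integer(n_trials),
         negative_count = sum(trials$outcome_bit))
}

#' Simulate a multi-lab cohort
#'
#' Generates an ordered cohort of participants with the requested per-lab
#' sizes.  Labs are laid out as consecutive blocks in the order given;
#' `collection_order` runs 1..N across the whole cohort.  The generation is a
#' pure function of the arguments: the same `seed` always yields the same
#' cohort.
#'
#' @param labs Per-lab sizes: either a named integer vector
#'   (`c(Germany = 1413, ...)`) or a data frame with columns `label` and
#'   `size`.  Defaults to the five-lab replication structure
#'   ([replication_labs()]).
#' @param n_trials Trials per participant (default 60).
#' @param p_negative Per-trial probability of a negative outcome; 0.5 is the
#'   fair-bit null, values below 0.5 inject an avoidance effect (see
#'   [p_negative_for_effect()]).
#' @param seed Integer seed; `NULL` leaves the random-number state untouched.
#' @param trials If `TRUE`, also return the trial-level records (as the
#'   `"trials"` attribute of the result).
#' @return Participant tibble with columns `participant_id`, `lab`,
#'   `collection_order`, `n_trials`, `negative_count`, ordered by
#'   `collection_order`.
#' @examples
#' cohort <- simulate_cohort(labs = c(A = 3, B = 2), seed = 42)
#' cohort$lab
#' @export
simulate_cohort <- function(labs = replication_labs(), n_trials = 60,
                            p_negative = 0.5, seed = NULL, trials = FALSE) {
  if (!is.data.frame(labs)) {
    if (is.null(names(labs)) || any(names(labs) == "")) {
      abort("`labs` must be a named vector or a data frame with `label` and `size`.")
    }
    labs <- tibble(label = names(labs), size = as.integer(labs))
  }
  if (!all(c("label", "size") %in% names(labs))) {
    abort("`labs` data frame must have columns `label` and `size`.")
  }
  if (anyDuplicated(labs$label)) abort("duplicate lab labels are not allowed.")
  sizes <- as.integer(labs$size)
  if (any(is.na(sizes)) || any(sizes < 1L)) abort("all lab sizes must be integers >= 1.")
  N <- sum(sizes)
  if (N < 2L) abort("total cohort size must be >= 2.")
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) abort("`n_trials` must be an integer >= 1.")
  .check_p(p_negative)
  if (!is.null(seed)) set.seed(as.integer(seed))

  # trial bits for the whole cohort at once: prestored fair, outcome biased,
  # live defined by the XOR identity
  prestored <- matrix(as.integer(runif(N * n_trials) < 0.5), N, n_trials)
  outcome <- matrix(as.integer(runif(N * n_trials) < p_negative), N, n_trials)
  counts <- as.integer(rowSums(outcome))

  cohort <- tibble(
    participant_id = sprintf("P%05d", seq_len(N)),
    lab = rep(labs$label, sizes),
    collection_order = seq_len(N),
    n_trials = n_trials,
    negative_count = counts)

  if (isTRUE(trials)) {
    live <- bitwXor(prestored, outcome)
    attr(cohort, "trials") <- tibble(
      participant_id = rep(cohort$participant_id, each = n_trials),
      trial_index = rep(seq_len(n_trials), times = N),
      prestored_bit = as.integer(t(prestored)),
      live_bit = as.integer(t(live)),
      outcome_bit = as.integer(t(outcome)),
      valence = ifelse(as.integer(t(outcome)) == 1L, "negative", "neutral"))
  }
  cohort
}

#' Simulate per-participant null counts
#'
#' Draws i.i.d. Binomial(`n_trials`, 0.5) negative-outcome counts, the
#' aggregate equivalent of simulating `n_participants * n_trials` fair bits
#' and summing each participant's outcomes.
#'
#' @param n_participants Number of participants (>= 2).
#' @param n_trials Trials per participant (>= 1).
#' @param seed Integer seed; `NULL` leaves the random-number state untouched.
#' @return Integer vector of length `n_participants`.
#' @examples
#' simulate_null_counts(5, seed = 1)
#' @export
simulate_null_counts <- function(n_participants, n_trials = 60, seed = NULL) {
  n_participants <- as.integer(n_participants)
  if (is.na(n_participants) || n_participants < 2L) {
    abort("`n_participants` must be an integer >= 2.")
  }
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) abort("`n_trials` must be an integer >= 1.")
  if (!is.null(seed)) set.seed(as.integer(seed))
  rbinom(n_participants, n_trials, 0.5)
}

#' Per-trial probability for a target standardized effect
#'
#' Solves for the per-trial negative-outcome probability p such that the
#' standardized avoidance effect of the per-participant count distribution,
#' d = (n_trials/2 - n_trials p) / sqrt(n_trials p (1 - p)), equals `d`.
#' A positive `d` means avoidance (counts below chance).
#'
#' @param d Target standardized effect size.
#' @param n_trials Trials per participant.
#' @return The per-trial probability (0.5 for `d = 0`; about 0.481 for
#'   `d = 0.3` at 60 trials).
#' @examples
#' p_negative_for_effect(0.3)
#' @export
p_negative_for_effect <- function(d, n_trials = 60) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d)) {
    abort("`d` must be a single finite number.")
  }
  if (d == 0) return(0.5)
  f <- function(p) (n_trials / 2 - n_trials * p) / sqrt(n_trials * p * (1 - p)) - d
  uniroot(f, interval = c(1e-6, 1 - 1e-6), tol = 1e-12)$root
}
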