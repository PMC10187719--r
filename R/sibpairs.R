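#' @keywords internal
eligible_siblings <- function(cohort) {
  ok <- cohort$role == "sibling" & !is.na(cohort$affected)
  if ("PRS_STD" %in% names(cohort)) ok <- ok & !is.na(cohort$PRS_STD)
  cohort[ok, , drop = FALSE]
}

# assemble a pair table with orientation metadata from row indices into `sibs`
make_pair_table <- function(sibs, ia, ib) {
  if (length(ia) == 0) {
    return(data.frame(fid = character(0), iid_a = character(0), iid_b = character(0),
                      discordant = logical(0), affected_older = logical(0),
                      affected_younger = logical(0), quintile_older = integer(0),
                      e4_older = logical(0), stringsAsFactors = FALSE))
  }
  grab <- function(col, idx) if (col %in% names(sibs)) sibs[[col]][idx] else rep(NA, length(idx))
  out <- data.frame(fid = sibs$fid[ia],
                    iid_a = sibs$iid[ia], iid_b = sibs$iid[ib],
                    affected_a = sibs$affected[ia], affected_b = sibs$affected[ib],
                    age_a = sibs$age[ia], age_b = sibs$age[ib],
                    prs_a = grab("PRS_STD", ia), prs_b = grab("PRS_STD", ib),
                    quintile_a = grab("QUINTILE", ia), quintile_b = grab("QUINTILE", ib),
                    decile_a = grab("DECILE", ia), decile_b = grab("DECILE", ib),
                    pctile_a = grab("PCTILE", ia), pctile_b = grab("PCTILE", ib),
                    e4_a = grab("apoe_e4", ia), e4_b = grab("apoe_e4", ib),
                    stringsAsFactors = FALSE)
  out$discordant <- out$affected_a != out$affected_b
  # older/younger: age ties broken by individual id for determinism
  a_older <- out$age_a > out$age_b |
    (out$age_a == out$age_b & out$iid_a < out$iid_b)
  pick <- function(xa, xb) ifelse(a_older, xa, xb)
  out$affected_older <- pick(out$affected_a, out$affected_b)
  out$affected_younger <- pick(out$affected_b, out$affected_a)
  out$quintile_older <- pick(out$quintile_a, out$quintile_b)
  out$decile_older <- pick(out$decile_a, out$decile_b)
  out$e4_older <- pick(out$e4_a, out$e4_b)
  # higher/lower PRS orientation; exact ties flagged, dropped by consumers
  out$prs_tie <- !is.na(out$prs_a) & out$prs_a == out$prs_b
  a_higher <- out$prs_a > out$prs_b
  hpick <- function(xa, xb) ifelse(a_higher, xa, xb)
  out$affected_higher <- hpick(out$affected_a, out$affected_b)
  out$quintile_higher <- hpick(out$quintile_a, out$quintile_b)
  out$decile_higher <- hpick(out$decile_a, out$decile_b)
  out$both_e4 <- out$e4_a & out$e4_b
  out$neither_e4 <- !out$e4_a & !out$e4_b
  out
}

#' Sample one random sibling pair per family
#'
#' From each family with at least two eligible siblings (non-missing affection
#' and, when present, PRS), draws one unordered pair uniformly at random.
#'
#' @param cohort a cohort data.frame.
#' @param seed integer seed; the draw is deterministic given it.
#' @return pair table (one row per pair) with orientation metadata
#'   (older/younger by age, higher/lower PRS, discordance); attribute
#'   \code{strategy = "one_per_family"}.
#' @export
sample_one_pair <- function(cohort, seed = 1L) {
  set.seed(seed)
  sibs <- eligible_siblings(cohort)
  ia <- integer(0); ib <- integer(0)
  for (rows in split(seq_len(nrow(sibs)), sibs$fid)) {
    if (length(rows) < 2) next
    pr <- sample(rows, 2)
    ia <- c(ia, pr[1]); ib <- c(ib, pr[2])
  }
  out <- make_pair_table(sibs, ia, ib)
  attr(out, "strategy") <- "one_per_family"
  out
}

#' Sample the maximum disjoint sibling pairing per family
#'
#' Randomly permutes each sibship and pairs consecutive members, yielding
#' \code{floor(s/2)} pairs per sibship of size \code{s}; with odd sizes one
#' uniformly random sibling is left out (recorded in attribute
#' \code{leftover}).
#'
#' @inheritParams sample_one_pair
#' @return pair table with attribute \code{strategy = "max_pairs"}.
#' @export
sample_max_pairs <- function(cohort, seed = 1L) {
  set.seed(seed)
  sibs <- eligible_siblings(cohort)
  ia <- integer(0); ib <- integer(0); leftover <- character(0)
  for (rows in split(seq_len(nrow(sibs)), sibs$fid)) {
    if (length(rows) < 2) {
      leftover <- c(leftover, sibs$iid[rows])
      next
    }
    perm <- if (length(rows) == 1) rows else sample(rows)
    np <- length(perm) %/% 2
    ia <- c(ia, perm[2 * seq_len(np) - 1])
    ib <- c(ib, perm[2 * seq_len(np)])
    if (length(perm) %% 2 == 1) leftover <- c(leftover, sibs$iid[perm[length(perm)]])
  }
  out <- make_pair_table(sibs, ia, ib)
  attr(out, "strategy") <- "max_pairs"
  attr(out, "leftover") <- leftover
  out
}

#' Replicate a pair-set statistic and summarize across replicates
#'
#' Draws \code{n_rep} independent replicate pair sets (seeds derived
#' deterministically from \code{seed}), evaluates a pure statistic of the pair
#' table on each, and reports the replicate mean and sample (n-1) standard
#' deviation. Replicates on which the statistic is undefined (\code{NA}) are
#' recorded as missing.
#'
#' @param stat function taking a pair table and returning a single number (or
#'   \code{NA} when undefined).
#' @param cohort cohort to pair.
#' @param strategy \code{"one_per_family"} or \code{"max_pairs"}.
#' @param n_rep number of replicates (default 100).
#' @param seed master seed.
#' @param name optional statistic label.
#' @return list of class \code{replicate_summary}: name, values, mean, sd,
#'   n_replicates, n_missing.
#' @export
replicate_estimate <- function(stat, cohort, strategy = c("one_per_family", "max_pairs"),
                               n_rep = 100, seed = 1L, name = "statistic") {
  strategy <- match.arg(strategy)
  sampler <- if (strategy == "one_per_family") sample_one_pair else sample_max_pairs
  seeds <- as.integer(seed) + seq_len(n_rep)
  values <- vapply(seeds, function(s) {
    v <- stat(sampler(cohort, seed = s))
    if (length(v) != 1) NA_real_ else as.numeric(v)
  }, numeric(1))
  structure(list(name = name, values = values,
                 mean = mean(values, na.rm = TRUE),
                 sd = stats::sd(values[!is.na(values)]),
                 n_replicates = n_rep, n_missing = sum(is.na(values)),
                 strategy = strategy),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("%s [%s, %d replicates%s]: %.4f (SD %.4f)\n",
              x$name, x$strategy, x$n_replicates,
              if (x$n_missing) sprintf(", %d missing", x$n_missing) else "",
              x$mean, x$sd))
  invisible(x)
}
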