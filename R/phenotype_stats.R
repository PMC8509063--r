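#' Pooled-count enrichment statistic F
#'
#' For a mutation observed `wt_count` times in the wild-type-phenotype
#' pool and `mut_count` times in the mutant-phenotype pool,
#' `F = 100 * (wt_count - mut_count) / (wt_count + mut_count)`.
#' F lies in \[-100, 100\]; it is positive when the mutation is
#' over-represented among reads with the wild-type phenotype (the toxin
#' still kills, i.e. the mutation is tolerated) and negative when it is
#' over-represented among mutant-phenotype reads (loss of function).
#'
#' @param wt_count,mut_count Non-negative counts (vectorised).
#' @return Numeric vector of F values (percent).
#' @examples
#' f_statistic(613, 221)  # 47.0
#' @export
f_statistic <- function(wt_count, mut_count) {
  if (any(wt_count < 0) || any(mut_count < 0))
    stop("counts must be non-negative")
  total <- wt_count + mut_count
  if (any(total == 0))
    stop("undefined statistic: wt_count + mut_count must be positive")
  100 * (wt_count - mut_count) / total
}

#' Classify a mutation from its F value
#'
#' A mutation whose |F| does not exceed the experimental error rate is an
#' incorrect sequence-phenotype assignment (ISPA) and is excluded from
#' tolerance analysis; `F > error_rate` marks a tolerated mutation
#' (enriched with the wild-type, toxin-active phenotype) and
#' `F < -error_rate` a deleterious (loss-of-function) one. The screen
#' used a 4% experimental error rate.
#'
#' @param f_value F values (percent), see [f_statistic()].
#' @param error_rate Experimental error band, in percent (default 4).
#' @return Character vector with values `"ispa"`, `"tolerated"` or
#'   `"deleterious"`.
#' @export
classify_mutation <- function(f_value, error_rate = 4) {
  stopifnot(error_rate >= 0)
  out <- rep("ispa", length(f_value))
  out[f_value > error_rate] <- "tolerated"
  out[f_value < -error_rate] <- "deleterious"
  out
}

#' Attach F values and classifications to a count table
#'
#' @param counts Data frame with `wt_count` and `mut_count` columns (a
#'   genotype or substitution table from [tally_counts()]).
#' @param error_rate Experimental error band in percent.
#' @param min_total Minimum total count; rows below it are dropped (guards
#'   low-coverage noise). The number dropped is kept in attribute
#'   `"n_low_coverage"`.
#' @return The table with added `f_value` and `classification` columns.
#' @export
mutation_stats <- function(counts, error_rate = 4, min_total = 1) {
  stopifnot(is.data.frame(counts),
            all(c("wt_count", "mut_count") %in% names(counts)))
  total <- counts$wt_count + counts$mut_count
  keep <- total >= max(min_total, 1)
  out <- counts[keep, , drop = FALSE]
  out$f_value <- f_statistic(out$wt_count, out$mut_count)
  out$classification <- classify_mutation(out$f_value, error_rate)
  rownames(out) <- NULL
  attr(out, "n_low_coverage") <- sum(!keep)
  attr(out, "error_rate") <- error_rate
  out
}

#' Per-position tolerance and criticality summary
#'
#' For every reference position, counts the classified single
#' substitutions that are tolerated versus deleterious (ISPAs are excluded
#' from both) and flags the position as critical when intolerant
#' mutations outnumber tolerant ones (ratio strictly greater than 1).
#'
#' @param sub_stats Substitution-level [mutation_stats()] table (must have
#'   `position` and `classification` columns).
#' @return Data frame with `position`, `tolerant_count`,
#'   `intolerant_count`, `critical`.
#' @export
position_summaries <- function(sub_stats) {
  stopifnot(all(c("position", "classification") %in% names(sub_stats)))
  s <- sub_stats[sub_stats$classification != "ispa", , drop = FALSE]
  pos <- sort(unique(s$position))
  tol <- vapply(pos, function(p)
    sum(s$position == p & s$classification == "tolerated"), 0)
  del <- vapply(pos, function(p)
    sum(s$position == p & s$classification == "deleterious"), 0)
  data.frame(position = pos, tolerant_count = tol, intolerant_count = del,
             critical = del > tol)
}

#' Deleterious single substitutions of a screen
#'
#' @param sub_stats Substitution-level [mutation_stats()] table.
#' @return Character vector of substitution strings classified deleterious.
#' @export
deleterious_singles <- function(sub_stats) {
  sub_stats$sub[sub_stats$classification == "deleterious"]
}

#' Find compensatory mutations
#'
#' A compensatory mutation is a multi-substitution genotype that shows the
#' wild-type phenotype (classified tolerated at the genotype level)
#' although it contains at least one substitution that is individually
#' deleterious. Following the screen's reporting convention, a minimum
#' wild-type-pool count may be required (the headline table used
#' count > 100).
#'
#' @param genotype_stats Genotype-level [mutation_stats()] table (columns
#'   `genotype`, `n_subs`, `wt_count`, `classification`).
#' @param deleterious Character vector of deleterious single substitutions
#'   (from [deleterious_singles()], or planted truth).
#' @param min_count Keep only records whose `wt_count` is strictly greater
#'   than this (default 0 = keep all).
#' @return Data frame with `genotype`, `n_subs`, `contained_deleterious`
#'   (comma-separated), `wt_count`, sorted by `wt_count` descending.
#' @export
find_compensatory <- function(genotype_stats, deleterious, min_count = 0) {
  stopifnot(all(c("genotype", "n_subs", "wt_count", "classification") %in%
                  names(genotype_stats)))
  g <- genotype_stats[genotype_stats$n_subs >= 2 &
                        genotype_stats$classification == "tolerated" &
                        genotype_stats$wt_count > min_count, , drop = FALSE]
  if (nrow(g) == 0L)
    return(data.frame(genotype = character(), n_subs = integer(),
                      contained_deleterious = character(),
                      wt_count = numeric()))
  contained <- vapply(genotype_subs(g$genotype), function(s)
    paste(intersect(s, deleterious), collapse = ","), "")
  g <- g[contained != "", , drop = FALSE]
  contained <- contained[contained != ""]
  o <- order(-g$wt_count, g$genotype)
  out <- data.frame(genotype = g$genotype[o], n_subs = g$n_subs[o],
                    contained_deleterious = contained[o],
                    wt_count = g$wt_count[o])
  rownames(out) <- NULL
  out
}

# report rounding: half away from zero, matching the screen's printed
# integer percentages (base round() would round half to even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Screen-level summary percentages
#'
#' @param n_expected Number of single variants the library design expects.
#' @param n_detected Number of expected single variants observed.
#' @param n_deleterious Number of detected singles classified deleterious.
#' @return Object of class `"screen_summary"`: list with the raw counts,
#'   full-precision percentages (`pct_detected`, `pct_tolerated`,
#'   `pct_deleterious_of_detected`, `pct_deleterious_of_expected`) and
#'   their half-up integer roundings (`*_rounded`).
#' @examples
#' summarize_screen(240, 233, 19)  # 97% detected, 92% tolerated, 8% deleterious
#' @export
summarize_screen <- function(n_expected, n_detected, n_deleterious) {
  if (n_expected <= 0) stop("n_expected must be positive")
  stopifnot(n_detected >= 0, n_deleterious >= 0, n_deleterious <= n_detected)
  pct_detected <- 100 * n_detected / n_expected
  pct_tolerated <- 100 * (n_detected - n_deleterious) / n_detected
  pct_del_det <- 100 * n_deleterious / n_detected
  pct_del_exp <- 100 * n_deleterious / n_expected
  out <- list(
    n_expected = n_expected, n_detected = n_detected,
    n_deleterious = n_deleterious,
    pct_detected = pct_detected,
    pct_tolerated = pct_tolerated,
    pct_deleterious_of_detected = pct_del_det,
    pct_deleterious_of_expected = pct_del_exp,
    pct_detected_rounded = round_half_up(pct_detected),
    pct_tolerated_rounded = round_half_up(pct_tolerated),
    pct_deleterious_rounded = round_half_up(pct_del_det))
  class(out) <- "screen_summary"
  out
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("Screen summary: %d / %d expected singles detected (%d%%)\n",
              x$n_detected, x$n_expected, x$pct_detected_rounded))
  cat(sprintf("  tolerated:   %d (%d%%)\n",
              x$n_detected - x$n_deleterious, x$pct_tolerated_rounded))
  cat(sprintf("  deleterious: %d (%d%% of detected, %d%% of expected)\n",
              x$n_deleterious, x$pct_deleterious_rounded,
              round_half_up(x$pct_deleterious_of_expected)))
  invisible(x)
}

#' Full phenotype analysis of a pooled screen
#'
#' Two-tier analysis of a [tally_counts()] object: substitution-level
#' statistics drive the deleterious calls and position summaries;
#' genotype-level statistics drive the compensatory-mutation detection.
#'
#' @param tally A [tally_counts()] (or [call_pools()]) result.
#' @param error_rate Experimental error band in percent (default 4).
#' @param min_total Minimum total count per record (see [mutation_stats()]).
#' @param min_compensatory_count Strict lower bound on the wild-type-pool
#'   count of reported compensatory genotypes.
#' @param expected_singles Optional character vector of expected single
#'   substitutions (library design); enables the detection summary.
#' @return Object of class `"screen_analysis"`: list with
#'   `substitution_stats`, `genotype_stats`, `positions`, `deleterious`,
#'   `compensatory`, `error_rate` and (when `expected_singles` is given)
#'   `summary`, a [summarize_screen()] object.
#' @export
screen_analysis <- function(tally, error_rate = 4, min_total = 1,
                            min_compensatory_count = 0,
                            expected_singles = NULL) {
  stopifnot(inherits(tally, "mutation_tally"))
  sub_stats <- mutation_stats(tally$substitutions, error_rate, min_total)
  gen_stats <- mutation_stats(tally$genotypes, error_rate, min_total)
  dels <- deleterious_singles(sub_stats)
  out <- list(
    substitution_stats = sub_stats,
    genotype_stats = gen_stats,
    positions = position_summaries(sub_stats),
    deleterious = dels,
    compensatory = find_compensatory(gen_stats, dels,
                                     min_compensatory_count),
    error_rate = error_rate)
  if (!is.null(expected_singles)) {
    detected <- intersect(expected_singles, sub_stats$sub)
    out$summary <- summarize_screen(length(expected_singles),
                                    length(detected),
                                    length(intersect(detected, dels)))
  }
  class(out) <- "screen_analysis"
  out
}

#' @export
print.screen_analysis <- function(x, ...) {
  cat("Pooled screen analysis (error band ", x$error_rate, "%)\n", sep = "")
  cat("  substitutions analysed:", nrow(x$substitution_stats), "\n")
  cat("  deleterious singles:   ", length(x$deleterious), "\n")
  cat("  critical positions:    ", sum(x$positions$critical), "of",
      nrow(x$positions), "\n")
  cat("  compensatory genotypes:", nrow(x$compensatory), "\n")
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' @export
summary.screen_analysis <- function(object, ...) {
  print(object)
  if (nrow(object$compensatory) > 0L) {
    cat("\nTop compensatory mutations:\n")
    print(head(object$compensatory, 10), row.names = FALSE)
  }
  invisible(object)
}
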