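#' Molecular-clock configuration for split-time conversion
#'
#' The symbiont clock bounds are the published per-generation substitution
#' rates for Wolbachia (slow bound from first/second codon positions, fast
#' bound from noncoding positions); the mitochondrial bounds are the two
#' widely used arthropod COI-style rates in percent uncorrected distance per
#' million years. `divergence_factor` converts a pairwise distance into
#' per-lineage branch length: 2 means divergence accrues on both branches.
#'
#' @param wolb_rate_min,wolb_rate_max Symbiont substitution-rate bounds
#'   (substitutions/site/host generation).
#' @param mito_rate_fast,mito_rate_slow Mitochondrial rate bounds
#'   (% distance per My).
#' @param generations_per_year_min,generations_per_year_max Host generations
#'   per year bounds.
#' @param divergence_factor 1 or 2 (default 2: both branches).
#' @return Object of class `clock_config`.
#' @export
clock_config <- function(wolb_rate_min = 2.76e-10, wolb_rate_max = 1.5e-9,
                         mito_rate_fast = 2.3, mito_rate_slow = 1.5,
                         generations_per_year_min = 1,
                         generations_per_year_max = 3,
                         divergence_factor = 2) {
  if (!(wolb_rate_min < wolb_rate_max))
    stop("wolb_rate_min must be below wolb_rate_max")
  if (!(mito_rate_slow < mito_rate_fast))
    stop("mito_rate_slow must be below mito_rate_fast")
  if (!(generations_per_year_min < generations_per_year_max))
    stop("generations_per_year bounds must be ordered")
  if (!divergence_factor %in% c(1, 2))
    stop("divergence_factor must be 1 or 2")
  structure(list(wolb_rate_min = wolb_rate_min, wolb_rate_max = wolb_rate_max,
                 mito_rate_fast = mito_rate_fast,
                 mito_rate_slow = mito_rate_slow,
                 generations_per_year_min = generations_per_year_min,
                 generations_per_year_max = generations_per_year_max,
                 divergence_factor = divergence_factor),
            class = "clock_config")
}

#' A [lo, hi] split-time interval
#'
#' @param lo,hi Interval bounds, 0 <= lo <= hi.
#' @param units One of "generations", "years", "My".
#' @return Object of class `time_range`.
#' @export
time_range <- function(lo, hi, units = c("generations", "years", "My")) {
  units <- match.arg(units)
  if (!(lo >= 0 && lo <= hi)) stop("need 0 <= lo <= hi")
  structure(list(lo = lo, hi = hi, units = units), class = "time_range")
}

#' @export
print.time_range <- function(x, ...) {
  cat("[", signif(x$lo, 5), ", ", signif(x$hi, 5), "] ", x$units, "\n",
      sep = "")
  invisible(x)
}

#' Midpoint and width of a time range
#' @param x A [time_range()].
#' @return Numeric scalar.
#' @export
midpoint <- function(x) (x$lo + x$hi) / 2

#' @rdname midpoint
#' @export
range_width <- function(x) x$hi - x$lo

#' Convert ANI to genetic distance
#'
#' @param ani ANI in percent, in [0, 100].
#' @return Distance `1 - ani/100`.
#' @export
ani_to_distance <- function(ani) {
  stopifnot(all(ani >= 0), all(ani <= 100))
  1 - ani / 100
}

#' Proportion of differing sites between two aligned sequences
#'
#' Positions where either base is not A/C/G/T (N, gap) are ignored.
#'
#' @param seq_a,seq_b Aligned sequences of equal length.
#' @return p-distance (differences / comparable sites).
#' @export
p_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences differ in length")
  cnt <- cpp_pdist_counts(seq_a, seq_b)
  if (cnt[["comparable"]] == 0) stop("no comparable sites")
  cnt[["diff"]] / cnt[["comparable"]]
}

#' Jukes-Cantor correction of a p-distance
#'
#' @param d Uncorrected distance(s), 0 <= d < 0.75.
#' @return Corrected distance `-(3/4) ln(1 - (4/3) d)`.
#' @export
jc_correct <- function(d) {
  if (any(d < 0) || any(d >= 0.75))
    stop("saturated distance: Jukes-Cantor correction requires d < 0.75")
  -0.75 * log(1 - 4 * d / 3)
}

#' Expected p-distance at a given Jukes-Cantor branch-length total
#'
#' The inverse of [jc_correct()]: the proportion of differing sites expected
#' after `d_jc` substitutions per site have accumulated between two
#' sequences (multiple hits allowed).
#'
#' @param d_jc Substitutions per site (total across both lineages).
#' @return Expected p-distance `(3/4)(1 - exp(-(4/3) d_jc))`.
#' @export
jc_expected_distance <- function(d_jc) {
  stopifnot(all(d_jc >= 0))
  0.75 * (1 - exp(-4 * d_jc / 3))
}

#' Symbiont split-time range from a corrected distance
#'
#' Generations: `[d_jc / (f r_max), d_jc / (f r_min)]` with `f` the
#' divergence factor; years additionally spread the generations bound over
#' the generations-per-year bounds (widest defensible interval).
#'
#' @param d_jc Jukes-Cantor-corrected distance (>= 0).
#' @param clock A [clock_config()].
#' @return List with `generations` and `years` [time_range()]s.
#' @export
wolb_split_range <- function(d_jc, clock = clock_config()) {
  stopifnot(d_jc >= 0)
  f <- clock$divergence_factor
  gen_lo <- d_jc / (f * clock$wolb_rate_max)
  gen_hi <- d_jc / (f * clock$wolb_rate_min)
  list(generations = time_range(gen_lo, gen_hi, "generations"),
       years = time_range(gen_lo / clock$generations_per_year_max,
                          gen_hi / clock$generations_per_year_min, "years"))
}

#' Mitochondrial split-time range from a distance
#'
#' `[100 d / rate_fast, 100 d / rate_slow]` My. The study's literal
#' procedure passes the Jukes-Cantor-corrected distance to these
#' uncorrected-distance clocks; pass the uncorrected distance instead for
#' the internally consistent alternative.
#'
#' @param d Distance (>= 0).
#' @param clock A [clock_config()].
#' @return A [time_range()] in My.
#' @export
mito_split_range <- function(d, clock = clock_config()) {
  stopifnot(d >= 0)
  time_range(100 * d / clock$mito_rate_fast,
             100 * d / clock$mito_rate_slow, "My")
}

#' Congruence verdict for two split-time ranges
#'
#' The two ranges are congruent when (1) the narrower range is completely
#' contained in the wider one, or (2) the midpoint of the wider range falls
#' inside the narrower one (bounds inclusive). Otherwise the first
#' (symbiont) range is "older" when its midpoint exceeds the second
#' (host) range's midpoint and "younger" when it is smaller; exact midpoint
#' equality without overlap counts as congruent.
#'
#' @param range_w Symbiont (or mitochondrial) [time_range()].
#' @param range_h Host [time_range()]; must use the same units.
#' @return One of "congruent", "older", "younger".
#' @export
classify_congruence <- function(range_w, range_h) {
  stopifnot(inherits(range_w, "time_range"), inherits(range_h, "time_range"))
  if (range_w$units != range_h$units)
    stop("unit mismatch: ", range_w$units, " vs ", range_h$units)
  if (range_width(range_w) <= range_width(range_h)) {
    s <- range_w; l <- range_h
  } else {
    s <- range_h; l <- range_w
  }
  contained <- s$lo >= l$lo && s$hi <= l$hi
  mid_inside <- midpoint(l) >= s$lo && midpoint(l) <= s$hi
  if (contained || mid_inside) return("congruent")
  mw <- midpoint(range_w); mh <- midpoint(range_h)
  if (mw > mh) "older" else if (mw < mh) "younger" else "congruent"
}

#' An isolate: one consensus sequence from one specimen
#'
#' @param sample Specimen/sample identifier.
#' @param species Host species.
#' @param strain Assigned strain (dereplicated representative id).
#' @return Object of class `isolate`.
#' @export
isolate <- function(sample, species, strain) {
  structure(list(sample = sample, species = species, strain = strain),
            class = "isolate")
}

#' Comparison category of two isolates
#'
#' 2 x 2 classification on (same species?, same strain?).
#'
#' @param isolate_a,isolate_b [isolate()]s carrying species and strain ids.
#' @return One of "intraspecific_intrastrain", "intraspecific_interstrain",
#'   "interspecific_intrastrain", "interspecific_interstrain".
#' @export
categorize <- function(isolate_a, isolate_b) {
  same_sp <- isolate_a$species == isolate_b$species
  same_st <- isolate_a$strain == isolate_b$strain
  paste0(if (same_sp) "intraspecific" else "interspecific", "_",
         if (same_st) "intrastrain" else "interstrain")
}

#' Envelope of a set of time ranges
#'
#' `[min of lows, max of highs]` across all comparisons in a category.
#'
#' @param ranges Non-empty list of [time_range()]s in the same units.
#' @return A [time_range()].
#' @export
range_summary <- function(ranges) {
  if (!length(ranges)) stop("empty set of ranges")
  units <- unique(vapply(ranges, function(r) r$units, character(1)))
  if (length(units) != 1) stop("unit mismatch across ranges")
  time_range(min(vapply(ranges, function(r) r$lo, numeric(1))),
             max(vapply(ranges, function(r) r$hi, numeric(1))), units)
}

#' Symbiont turnover rate from sister-pair strain differences
#'
#' Counts strain differences as the symmetric difference of the two species'
#' strain sets, divides by the summed branch length
#' (`divergence_factor x split_gen` per pair) and scales to events per
#' million host generations.
#'
#' @param input A `turnover_input`: list with element `pairs`, each a list
#'   with `strains_a`, `strains_b` (character vectors) and `split_gen`
#'   (> 0). [simulate_turnover_history()] produces one.
#' @param clock A [clock_config()] (supplies the divergence factor).
#' @return Rate in acquisition-or-loss events per million host generations.
#' @export
turnover_rate <- function(input, clock = clock_config()) {
  pairs <- input$pairs
  stopifnot(length(pairs) >= 1)
  D <- sum(vapply(pairs, function(p) {
    length(setdiff(p$strains_a, p$strains_b)) +
      length(setdiff(p$strains_b, p$strains_a))
  }, numeric(1)))
  G <- sum(vapply(pairs, function(p) {
    stopifnot(p$split_gen > 0)
    clock$divergence_factor * p$split_gen
  }, numeric(1)))
  if (G == 0) stop("total branch length is zero")
  1e6 * D / G
}

#' Expected waiting time between turnover events
#'
#' @param rate Turnover rate (events per million host generations).
#' @param gpy Host generations per year.
#' @return Waiting time in My.
#' @export
waiting_time <- function(rate, gpy) {
  stopifnot(rate > 0, gpy > 0)
  1 / (rate * gpy)
}

#' Date and classify a set of isolate comparisons
#'
#' For each pair of isolates: category, symbiont split range (from the
#' consensus-pair ANI or p-distance via Jukes-Cantor), and congruence
#' verdict against the supplied host split range.
#'
#' @param comparisons data.frame with columns sample_a, species_a, strain_a,
#'   sample_b, species_b, strain_b, and either `ani` (percent) or
#'   `distance`; plus host_lo, host_hi (host split range, years).
#' @param clock A [clock_config()].
#' @return data.frame with category, wolb_lo, wolb_hi (years) and verdict.
#' @export
date_comparisons <- function(comparisons, clock = clock_config()) {
  d <- if ("distance" %in% names(comparisons)) comparisons$distance else
    ani_to_distance(comparisons$ani)
  out <- vector("list", nrow(comparisons))
  for (i in seq_len(nrow(comparisons))) {
    rng <- wolb_split_range(jc_correct(d[i]), clock)$years
    host <- time_range(comparisons$host_lo[i], comparisons$host_hi[i],
                       "years")
    out[[i]] <- data.frame(
      category = categorize(
        isolate(comparisons$sample_a[i], comparisons$species_a[i],
                comparisons$strain_a[i]),
        isolate(comparisons$sample_b[i], comparisons$species_b[i],
                comparisons$strain_b[i])),
      wolb_lo = rng$lo, wolb_hi = rng$hi,
      verdict = classify_congruence(rng, host),
      stringsAsFactors = FALSE)
  }
  cbind(comparisons, do.call(rbind, out))
}
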