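#' Gamete-sampling model
#'
#' Closed-form model of how many unique cells and meioses a sequenced
#' sperm sample represents. Defaults are the study-scale values: 2.5e6
#' cells sampled from a 2e8-cell specimen (~5e7 meioses), 3.2 Gb genome,
#' 18 kb mean fragment length, 50x coverage, 586 ng library input at
#' 1.096e-21 g/bp. Each meiosis contributes 4 daughter cells; the number
#' sampled per meiosis is Binomial(4, p) with
#' p = n_cells_sampled / n_cells_specimen.
#'
#' @param n_cells_sampled Cells taken for DNA extraction.
#' @param n_cells_specimen Cells in the specimen.
#' @param n_meioses Meioses represented in the specimen.
#' @param genome_size Haploid genome size (bp).
#' @param fragment_len_mean,fragment_len_sd Fragment length (bp).
#' @param coverage Fold sequencing coverage.
#' @param library_mass DNA mass loaded for sequencing (g).
#' @param mass_per_bp Mass of one bp (g).
#' @return A list of class `gamete_model`.
#' @export
gamete_model <- function(n_cells_sampled = 2.5e6, n_cells_specimen = 2e8,
                         n_meioses = 5e7, genome_size = 3.2e9,
                         fragment_len_mean = 18000, fragment_len_sd = 2500,
                         coverage = 50, library_mass = 586e-9,
                         mass_per_bp = 1.096e-21) {
  stopifnot(n_cells_sampled > 0, n_cells_specimen > 0, n_meioses > 0,
            genome_size > 0, fragment_len_mean > 0, coverage >= 0,
            library_mass > 0, mass_per_bp > 0)
  p <- n_cells_sampled / n_cells_specimen
  if (p <= 0 || p >= 1) stop("sampling probability must lie in (0, 1)")
  structure(list(n_cells_sampled = n_cells_sampled,
                 n_cells_specimen = n_cells_specimen, n_meioses = n_meioses,
                 genome_size = genome_size,
                 fragment_len_mean = fragment_len_mean,
                 fragment_len_sd = fragment_len_sd, coverage = coverage,
                 library_mass = library_mass, mass_per_bp = mass_per_bp,
                 daughter_cells_per_meiosis = 4L, p = p),
            class = "gamete_model")
}

#' Distribution of sampled daughter cells per meiosis
#'
#' Binomial(4, p) pmf over k = 0..4 sampled cells per meiotic event (the
#' exact hypergeometric is approximated binomially, accurate for large
#' specimens). Sums to 1 to machine precision.
#'
#' @param model A [gamete_model()].
#' @return Named numeric vector, `k0`..`k4`.
#' @export
sampled_cell_distribution <- function(model) {
  stats::setNames(stats::dbinom(0:4, size = 4, prob = model$p),
                  paste0("k", 0:4))
}

#' Singleton probability and counts
#'
#' P(exactly one daughter cell of a meiosis is sampled), the expected
#' number of singleton meioses (`n_meioses * P(X=1)`), and the fraction of
#' sampled cells that are singletons (singleton count / cells sampled).
#'
#' @param model A [gamete_model()].
#' @return A list: `p_singleton`, `singleton_count`,
#'   `singleton_cell_fraction`.
#' @export
singleton_probability <- function(model) {
  p1 <- stats::dbinom(1, size = 4, prob = model$p)
  cnt <- model$n_meioses * p1
  list(p_singleton = p1, singleton_count = cnt,
       singleton_cell_fraction = cnt / model$n_cells_sampled)
}

#' Reads per cell and the intermediate library quantities
#'
#' @param model A [gamete_model()].
#' @return A list: `gdna_bp` (cells x genome size), `gdna_fragments`,
#'   `library_bp` (`library_mass / mass_per_bp`), `library_fragments`,
#'   `bp_sequenced` (`coverage x genome_size`), `reads_sequenced`
#'   (`bp_sequenced / fragment_len_mean`), `reads_per_cell`
#'   (`reads_sequenced / n_cells_sampled`).
#' @export
reads_per_cell <- function(model) {
  if (model$fragment_len_mean <= 0) stop("fragment length must be positive")
  gdna_bp <- model$n_cells_sampled * model$genome_size
  library_bp <- model$library_mass / model$mass_per_bp
  bp_sequenced <- model$coverage * model$genome_size
  reads_sequenced <- bp_sequenced / model$fragment_len_mean
  list(gdna_bp = gdna_bp,
       gdna_fragments = gdna_bp / model$fragment_len_mean,
       library_bp = library_bp,
       library_fragments = library_bp / model$fragment_len_mean,
       bp_sequenced = bp_sequenced,
       reads_sequenced = reads_sequenced,
       reads_per_cell = reads_sequenced / model$n_cells_sampled)
}

#' Per-gamete insertion rate with exact Poisson confidence interval
#'
#' Rate = events / fold-coverage: under the single-read detection regime
#' each read samples one distinct gamete, so fold-coverage counts gametes
#' surveyed. The CI is the exact (Garwood) Poisson interval on the event
#' count, divided by coverage.
#'
#' @param n_events Observed insertion events (>= 0).
#' @param coverage Fold coverage (> 0), the effective gametes surveyed.
#' @param conf Confidence level (default 0.95).
#' @param sample_id,age,group Optional metadata carried through.
#' @return A list of class `sample_rate`: `sample_id`, `age`, `group`,
#'   `n_events`, `n_gametes`, `rate`, `ci_low`, `ci_high`.
#' @export
per_gamete_rate <- function(n_events, coverage, conf = 0.95,
                            sample_id = NA_character_, age = NA_real_,
                            group = NA_character_) {
  if (n_events < 0) stop("n_events must be non-negative")
  if (coverage <= 0) stop("coverage must be positive")
  a <- (1 - conf) / 2
  lo <- if (n_events == 0) 0 else stats::qchisq(a, 2 * n_events) / 2
  hi <- stats::qchisq(1 - a, 2 * (n_events + 1)) / 2
  structure(list(sample_id = sample_id, age = age, group = group,
                 n_events = n_events, n_gametes = coverage,
                 rate = n_events / coverage,
                 ci_low = lo / coverage, ci_high = hi / coverage),
            class = "sample_rate")
}

#' Pooled rate over samples
#'
#' `sum(events) / sum(coverage)`; invariant to how the samples are
#' partitioned.
#'
#' @param samples List of [per_gamete_rate()] objects.
#' @return Pooled rate (events/gamete).
#' @export
pooled_rate <- function(samples) {
  ev <- sum(vapply(samples, `[[`, numeric(1), "n_events"))
  cov <- sum(vapply(samples, `[[`, numeric(1), "n_gametes"))
  ev / cov
}

#' Ordinary least squares of per-gamete rate on donor age
#'
#' Regresses rate on age over the included groups (default: healthy donors
#' only) and reports the slope (additional insertions per gamete per year),
#' intercept, R-squared and the two-sided t-test p-value on the slope.
#'
#' @param samples List of [per_gamete_rate()] objects with `age` and
#'   `group` set.
#' @param include_groups Groups to include (default `"healthy"`).
#' @return A list: `slope`, `intercept`, `r_squared`, `p_value`, `n`,
#'   `fit` (the `lm` object).
#' @export
age_regression <- function(samples, include_groups = "healthy") {
  keep <- vapply(samples, function(s)
    is.na(include_groups[1]) || s$group %in% include_groups, logical(1))
  df <- data.frame(
    age = vapply(samples[keep], `[[`, numeric(1), "age"),
    rate = vapply(samples[keep], `[[`, numeric(1), "rate"))
  if (nrow(df) < 3) stop("need at least 3 samples")
  if (length(unique(df$age)) < 2) stop("constant ages: singular design")
  fit <- stats::lm(rate ~ age, data = df)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)["age"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients["age", "Pr(>|t|)"],
       n = nrow(df), fit = fit)
}

#' Two-tailed rate outlier test against a pooled cohort
#'
#' Tests whether one sample's per-gamete rate departs from the cohort's
#' pooled rate. The default z formulation uses the Poisson variance of the
#' pooled rate scaled to the sample's coverage:
#' `z = (rate - pooled) / sqrt(pooled / coverage)`, two-tailed normal
#' p-value. `method = "exact"` instead uses the two-sided exact Poisson
#' test of the sample's event count against expectation
#' `pooled * coverage` (preferable at small counts, where the z-test is
#' conservative).
#'
#' @param sample A [per_gamete_rate()] object.
#' @param cohort List of [per_gamete_rate()] objects pooled for the
#'   baseline (exclude or include `sample` per your design).
#' @param method `"z"` (default) or `"exact"`.
#' @return A list: `p_value`, `z` (`NA` for exact), `pooled_rate`.
#' @export
rate_outlier_test <- function(sample, cohort, method = c("z", "exact")) {
  method <- match.arg(method)
  if (length(cohort) == 0) stop("empty cohort")
  lambda <- pooled_rate(cohort)
  if (method == "z") {
    se <- sqrt(lambda / sample$n_gametes)
    z <- (sample$rate - lambda) / se
    list(p_value = 2 * stats::pnorm(-abs(z)), z = z, pooled_rate = lambda)
  } else {
    pt <- stats::poisson.test(sample$n_events,
                              T = sample$n_gametes * lambda)
    list(p_value = pt$p.value, z = NA_real_, pooled_rate = lambda)
  }
}

#' Load the bundled de novo Alu insertion feature table
#'
#' A curated validation table of published single-read de novo Alu
#' insertion calls from human sperm long-read data (37 rows): chromosome
#' (haplotype-suffixed assembly contig), position, subfamily, orientation,
#' TSD length and sequence, poly(A) tail length and impurity fraction.
#' Used by the validation suite: recomputing TSD length from the printed
#' sequence must reproduce the printed length column, and the column
#' summaries (TSD min/median, poly(A) median/max) are fixed points of the
#' feature definitions.
#'
#' @return A `data.frame` with columns `chromosome`, `position`,
#'   `subfamily`, `orientation`, `tsd_length`, `tsd_sequence`,
#'   `polya_length`, `polya_impurity`.
#' @export
load_insertion_table <- function() {
  path <- system.file("extdata", "denovo_alu_insertions.tsv",
                      package = "gameteMEI", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
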