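#' Configuration for the synthetic meront cohort generator
#'
#' Bundles every tunable of the simulated world into one validated object.
#' Defaults encode the measured biology of the two microsporidian species:
#'
#' * mitosome minor axes (diameters) uniform on 47–119 nm and major axes
#'   (tip-to-tip lengths) uniform on 78–267 nm, with `L >= 2r` enforced by
#'   rejection;
#' * *E. cuniculi*: mitosome count per nucleus follows
#'   `N = max(1, round(intercept + slope * V_nuc + eps))` with Gaussian
#'   `eps`, calibrated so the cohort mean is 7.4 and aggregate mitosome
#'   volume scales with nucleus volume; 92% of mitosomes tethered to a
#'   spindle pole body, split as evenly as possible across the two;
#' * *T. hominis*: a roughly constant count uniform on 14–18 per cell, with
#'   a stage-dependent tether fraction rising to 0.73 at the prespore
#'   stage.
#'
#' @param species `"ecuniculi"` or `"thominis"`.
#' @param n_cells Number of cells to simulate (per stage, for stage
#'   series).
#' @param seed Root RNG seed; every cell derives an independent substream
#'   keyed by its index, so cohorts are reproducible independent of
#'   generation order.
#' @param minor_range_nm,major_range_nm Uniform sampling ranges for the
#'   mitosome minor axis (diameter `2r`) and major axis (total length `L`),
#'   nm.
#' @param nucleus_radius_range_nm Uniform range for the nucleus radius, nm.
#' @param cytoplasm_offset_nm Cell radius minus nucleus radius, nm; the
#'   cytoplasm is the concentric spherical shell between the two.
#' @param mspb_radius_range_nm Uniform range for the half-sphere mSPB
#'   radius, nm.
#' @param contact_max_nm Contact criterion: a mitosome counts as tethered
#'   when the surface-to-surface distance between its nearer cap and the
#'   mSPB cap is at most this (10 nm, below membrane resolution at the
#'   section thickness modelled here).
#' @param tether_jitter_deg Half-angle of the cone around the outward
#'   nuclear normal within which tethered mitosome axes are drawn.
#' @param count_model List with `intercept`, `slope_per_nm3`, `sd` for the
#'   *E. cuniculi* count model.
#' @param count_range Integer range for the *T. hominis* per-cell count.
#' @param tether_fraction Probability that a mitosome is tethered
#'   (*E. cuniculi* default 0.92).
#' @param partition_mode `"ordered_even"` (counts on the two SPBs differ by
#'   at most one) or `"binomial_random"` (each tethered mitosome picks a
#'   side independently with probability 1/2).
#' @param perturbation `"none"` or `"dynamin_inhibition"` (see
#'   [apply_dynamin_inhibition()]).
#' @param stage_schedule Named numeric vector mapping developmental stage
#'   to tether fraction (*T. hominis*); the default ends at 0.73 for the
#'   prespore stage.
#' @return A validated list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_cells = 10, seed = 1)
#' cfg$tether_fraction
#' @export
cohort_config <- function(species = c("ecuniculi", "thominis"),
                          n_cells = 18,
                          seed = 1,
                          minor_range_nm = c(47, 119),
                          major_range_nm = c(78, 267),
                          nucleus_radius_range_nm = NULL,
                          cytoplasm_offset_nm = NULL,
                          mspb_radius_range_nm = c(35, 60),
                          contact_max_nm = 10,
                          tether_jitter_deg = 25,
                          count_model = NULL,
                          count_range = c(14L, 18L),
                          tether_fraction = 0.92,
                          partition_mode = c("ordered_even",
                                             "binomial_random"),
                          perturbation = c("none", "dynamin_inhibition"),
                          stage_schedule = NULL) {
  species <- match.arg(species)
  partition_mode <- match.arg(partition_mode)
  perturbation <- match.arg(perturbation)
  nucleus_radius_range_nm <- nucleus_radius_range_nm %||%
    switch(species, ecuniculi = c(300, 500), thominis = c(450, 700))
  cytoplasm_offset_nm <- cytoplasm_offset_nm %||%
    switch(species, ecuniculi = 400, thominis = 500)
  # slope calibrated so E[N] = 7.4 at the default nucleus-volume
  # distribution, with half the mean carried by the V_nuc term
  count_model <- count_model %||% {
    v_mean <- mean_nucleus_volume(nucleus_radius_range_nm)
    list(intercept = 3.7, slope_per_nm3 = 3.7 / v_mean, sd = 1.2)
  }
  stage_schedule <- stage_schedule %||%
    c(early = 0.10, multinucleate1 = 0.30, multinucleate2 = 0.45,
      multinucleate3 = 0.60, prespore = 0.73)
  cfg <- structure(
    list(species = species, n_cells = as.integer(n_cells),
         seed = as.integer(seed),
         minor_range_nm = as.numeric(minor_range_nm),
         major_range_nm = as.numeric(major_range_nm),
         nucleus_radius_range_nm = as.numeric(nucleus_radius_range_nm),
         cytoplasm_offset_nm = as.numeric(cytoplasm_offset_nm),
         mspb_radius_range_nm = as.numeric(mspb_radius_range_nm),
         contact_max_nm = as.numeric(contact_max_nm),
         tether_jitter_deg = as.numeric(tether_jitter_deg),
         count_model = count_model,
         count_range = as.integer(count_range),
         tether_fraction = as.numeric(tether_fraction),
         partition_mode = partition_mode,
         perturbation = perturbation,
         stage_schedule = stage_schedule,
         format_version = ms_format_version()),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

# exact E[(4/3) pi R^3] for R uniform on [a, b]
mean_nucleus_volume <- function(range_nm) {
  a <- range_nm[[1]]; b <- range_nm[[2]]
  4 / 3 * pi * (b^4 - a^4) / (4 * (b - a))
}

#' @rdname cohort_config
#' @param config Object to validate.
#' @export
validate_cohort_config <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("expected a `cohort_config` object")
  }
  chk_range <- function(x, what) {
    if (length(x) != 2 || any(!is.finite(x)) || any(x <= 0) || x[1] > x[2]) {
      abort(paste0("invalid ", what, ": need two positive, ordered values"))
    }
  }
  chk_range(config$minor_range_nm, "minor_range_nm")
  chk_range(config$major_range_nm, "major_range_nm")
  chk_range(config$nucleus_radius_range_nm, "nucleus_radius_range_nm")
  chk_range(config$mspb_radius_range_nm, "mspb_radius_range_nm")
  if (config$major_range_nm[2] < config$minor_range_nm[1]) {
    abort(paste0("infeasible axis ranges: no major axis can reach the ",
                 "smallest minor axis (L >= 2r is impossible)"))
  }
  probs <- c(config$tether_fraction, config$stage_schedule)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("tether fractions must be probabilities in [0, 1]")
  }
  if (config$n_cells < 0) abort("n_cells must be >= 0")
  if (config$cytoplasm_offset_nm <= 0) {
    abort("cytoplasm_offset_nm must be > 0 (cytoplasm radius > nucleus)")
  }
  if (config$contact_max_nm < 0) abort("contact_max_nm must be >= 0")
  config
}
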