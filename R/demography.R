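#' Three-population domestication demography
#'
#' Two-split, two-bottleneck model: an ancestral wild population of diploid
#' size `N_anc` founds a domesticated lineage `T_dom` generations before
#' present through a bottleneck (`N_bottleneck1` diploids for
#' `D_bottleneck1` generations); that lineage splits at `T_split` into two
#' breeds, each passing through a breed-formation bottleneck
#' (`N_bottleneck2` for `D_bottleneck2` generations) before recovering to
#' `N_breed`. After `T_split` the two breeds exchange migrants at a symmetric
#' per-lineage per-generation probability `m`. Between the end of the
#' domestication bottleneck and the breed split the domestic lineage is held
#' at `N_breed`.
#'
#' Defaults give a wild-boar-like ancestor (Ne = 10,000), domestication about
#' 10 ky ago at a 5-year generation time (2,000 generations, inside the 5-15
#' ky window usually quoted for pigs), modern breed formation about 200 years
#' ago (40 generations), and weak ongoing between-breed gene flow. They are
#' illustrative of the fitted model class, not re-inferred estimates.
#'
#' @param N_anc diploid size of the ancestral/wild population
#' @param T_dom generations before present of the wild/domestic split
#' @param T_split generations before present of the breed split
#'   (`T_dom >= T_split >= 0`; zero collapses the corresponding split)
#' @param N_bottleneck1,D_bottleneck1 size and duration of the domestication
#'   bottleneck (starts at `T_dom`)
#' @param N_bottleneck2,D_bottleneck2 size and duration of each
#'   breed-formation bottleneck (starts at `T_split`)
#' @param N_breed present-day diploid breed size
#' @param m symmetric migration probability per lineage per generation
#'   between the two breeds after `T_split`
#' @param mu per-site per-generation mutation rate
#' @param r per-adjacent-base per-generation recombination rate (used by the
#'   forward simulator only; the coalescent mode has no recombination)
#' @return an object of class `DemographyModel`
#' @export
demography_model <- function(N_anc = 10000, T_dom = 2000, T_split = 40,
                             N_bottleneck1 = 250, D_bottleneck1 = 200,
                             N_bottleneck2 = 50, D_bottleneck2 = 10,
                             N_breed = 1000, m = 0.001,
                             mu = 2.5e-8, r = 1e-8) {
  x <- structure(
    list(N_anc = N_anc, T_dom = T_dom, T_split = T_split,
         N_bottleneck1 = N_bottleneck1, D_bottleneck1 = D_bottleneck1,
         N_bottleneck2 = N_bottleneck2, D_bottleneck2 = D_bottleneck2,
         N_breed = N_breed, m = m, mu = mu, r = r),
    class = "DemographyModel")
  validate_demography(x)
  x
}

validate_demography <- function(x) {
  with(x, {
    for (nm in c("N_anc", "N_bottleneck1", "N_bottleneck2", "N_breed")) {
      if (x[[nm]] < 1) stop(sprintf("%s must be >= 1", nm), call. = FALSE)
    }
    if (D_bottleneck1 < 0 || D_bottleneck2 < 0) {
      stop("bottleneck durations must be >= 0", call. = FALSE)
    }
    if (m < 0 || m >= 1) stop("m must satisfy 0 <= m < 1", call. = FALSE)
    if (T_split < 0 || T_dom < T_split) {
      stop("times must satisfy T_dom >= T_split >= 0", call. = FALSE)
    }
    if (mu < 0 || r < 0) stop("mu and r must be >= 0", call. = FALSE)
  })
  invisible(x)
}

#' @export
print.DemographyModel <- function(x, ...) {
  cat("DemographyModel (two splits, two bottlenecks, breed migration)\n")
  cat(sprintf("  wild/domestic split %g gen ago; breed split %g gen ago\n",
              x$T_dom, x$T_split))
  cat(sprintf("  N_anc=%g  bottleneck1 %g x %g gen  bottleneck2 %g x %g gen  N_breed=%g\n",
              x$N_anc, x$N_bottleneck1, x$D_bottleneck1,
              x$N_bottleneck2, x$D_bottleneck2, x$N_breed))
  cat(sprintf("  m=%g  mu=%g  r=%g\n", x$m, x$mu, x$r))
  invisible(x)
}

#' Rescale a demography for desk-scale forward simulation
#'
#' Standard population-genetic rescaling by a factor `Q`: sizes and times are
#' divided by `Q` while `mu`, `r` (and any selection coefficient, rescaled at
#' sweep construction) are multiplied by `Q`, preserving N*mu, N*r, N*s and
#' times in units of N.
#'
#' @param model a `DemographyModel`
#' @param Q scaling factor (> 1 shrinks the model)
#' @return a rescaled `DemographyModel` with attribute `scale_Q`
#' @export
scale_demography <- function(model, Q) {
  stopifnot(inherits(model, "DemographyModel"), Q > 0)
  out <- demography_model(
    N_anc = max(1, round(model$N_anc / Q)),
    T_dom = round(model$T_dom / Q),
    T_split = round(model$T_split / Q),
    N_bottleneck1 = max(1, round(model$N_bottleneck1 / Q)),
    D_bottleneck1 = round(model$D_bottleneck1 / Q),
    N_bottleneck2 = max(1, round(model$N_bottleneck2 / Q)),
    D_bottleneck2 = round(model$D_bottleneck2 / Q),
    N_breed = max(1, round(model$N_breed / Q)),
    m = min(model$m * Q, 0.5),
    mu = model$mu * Q, r = model$r * Q)
  attr(out, "scale_Q") <- Q
  out
}

#' Specification of a planted selective sweep
#'
#' @param target_population breed label carrying the beneficial allele
#' @param position base coordinate (0-based) of the selected site
#' @param s additive selection coefficient per generation (diploid fitnesses
#'   1, 1+s, 1+2s in the target population)
#' @param onset_generation generations before present at which the allele is
#'   introduced
#' @param mode `"complete"` (condition on fixation at sampling), `"partial"`
#'   (condition on an intermediate frequency among the sampled haplotypes) or
#'   `"track"` (no conditioning; diagnostic trajectory recording only)
#' @param target_frequency for partial mode, the frequency around which
#'   sampling is conditioned (in (0,1), typically 0.2-0.8)
#' @param frequency_tol half-width of the acceptance band for partial mode
#' @param initial_frequency optional starting frequency of the introduced
#'   allele; the default introduces a single copy
#' @return an object of class `SweepSpec`
#' @export
sweep_spec <- function(target_population, position, s,
                       onset_generation,
                       mode = c("complete", "partial", "track"),
                       target_frequency = 0.5, frequency_tol = 0.1,
                       initial_frequency = NULL) {
  mode <- match.arg(mode)
  if (s <= 0) stop("s must be > 0", call. = FALSE)
  if (mode == "partial" &&
      (target_frequency <= 0 || target_frequency >= 1)) {
    stop("target_frequency must lie in (0, 1) for partial mode",
         call. = FALSE)
  }
  structure(
    list(target_population = target_population, position = position, s = s,
         onset_generation = onset_generation, mode = mode,
         target_frequency = target_frequency, frequency_tol = frequency_tol,
         initial_frequency = initial_frequency),
    class = "SweepSpec")
}
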