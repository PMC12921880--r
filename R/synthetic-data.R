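#' Generate a synthetic degradation time series
#'
#' Draws concentrations from an SFO or hockey-stick truth curve with
#' additive Gaussian noise truncated at zero, on the standard bench
#' sampling schedule (0, 0.5, 1, 2, 5, 7, 14, 21, 28 days) starting from
#' 10 mg/L, the usual spiking level of bench biodegradation assays.
#'
#' @param model `"sfo"` or `"hs"`.
#' @param m0 Initial concentration (mg/L), default 10.
#' @param k SFO rate constant (1/day).
#' @param k1,k2,tb Hockey-stick parameters (fast/slow rates, breakpoint).
#' @param times Sampling times (days).
#' @param sd Additive Gaussian noise standard deviation (mg/L); 0 gives
#'   the exact model curve.
#' @param seed Integer seed (mandatory).
#' @param compound_id Label carried into the output.
#' @return A tibble with columns `time_days`, `concentration_mg_per_L`,
#'   `compound_id`, ready for [fit_sfo()] / [fit_hs()].
#' @examples
#' gen_degradation(model = "sfo", k = 0.33, sd = 0, seed = 1)
#' @export
gen_degradation <- function(model = c("sfo", "hs"), m0 = 10, k = 0.33,
                            k1 = 1.05, k2 = 0.002, tb = 1,
                            times = c(0, 0.5, 1, 2, 5, 7, 14, 21, 28),
                            sd = 0.2, seed, compound_id = "DCF") {
  model <- match.arg(model)
  if (missing(seed)) abort("`seed` is mandatory.")
  check_nonneg(sd, "sd")
  truth <- switch(model,
                  sfo = predict_sfo(m0, k, times),
                  hs = predict_hs(m0, k1, k2, tb, times))
  conc <- withr::with_seed(as.integer(seed),
                           pmax(truth + rnorm(length(times), 0, sd), 0))
  tibble::tibble(time_days = times, concentration_mg_per_L = conc,
                 compound_id = compound_id)
}

#' Generate synthetic dose-response viability data
#'
#' Viability follows the quadratic-in-log10-dose truth
#' `y = a u^2 + b u + c` with additive Gaussian noise floored at 0, on the
#' standard growth-inhibition dose ladder 10-5000 mg/L measured in
#' duplicate. The default truth stays non-negative over that ladder and
#' crosses 50% viability near 500 mg/L.
#'
#' @param a,b,c Quadratic truth coefficients on the log10-dose scale.
#' @param concentrations Dose ladder (mg/L), default
#'   `c(10, 100, 500, 1000, 3000, 5000)`.
#' @param replicates Measurements per dose (default 2).
#' @param sd Gaussian noise sd in viability percentage points.
#' @param seed Integer seed (mandatory).
#' @return A tibble with `concentration_mg_per_L` and `viability_pct`.
#' @export
gen_dose_response <- function(a = -8, b = 5, c = 95,
                              concentrations = c(10, 100, 500, 1000,
                                                 3000, 5000),
                              replicates = 2, sd = 5, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  check_nonneg(sd, "sd")
  if (any(concentrations <= 0)) abort("Concentrations must be > 0.")
  conc <- rep(concentrations, each = replicates)
  u <- log10(conc)
  truth <- a * u^2 + b * u + c
  viab <- withr::with_seed(as.integer(seed),
                           pmax(truth + rnorm(length(conc), 0, sd), 0))
  tibble::tibble(concentration_mg_per_L = conc, viability_pct = viab)
}

#' Generate a synthetic Microtox-style luminescence table
#'
#' Builds a dilution-series record set whose gamma follows the log-linear
#' truth `gamma = (dilution / ec50_true)^slope`. Initial intensities `i0`
#' and the 15-min readings carry multiplicative log-normal noise of
#' coefficient of variation `cv`; toxicant-free control pairs with decay
#' ratio `f_true` are included. The default 1:2 dilution ladder is
#' 90.9, 45.45, 22.73 and 11.36 % v/v.
#'
#' @param ec50_true True EC50 (% v/v).
#' @param slope Log10-gamma slope per log10 dilution (default 2).
#' @param dilutions Dilution ladder (% v/v).
#' @param f_true Control luminescence decay ratio `i15/i0` (default 0.9).
#' @param i0_nominal Nominal initial intensity (instrument units).
#' @param cv Multiplicative noise coefficient of variation (0 = exact).
#' @param replicates Number of sample replicates (default 1).
#' @param n_controls Control pairs (default 2).
#' @param seed Integer seed (mandatory).
#' @return A tibble with columns `role`, `dilution_pct`, `i0`, `i15`,
#'   `replicate`, ready for [microtox()] / [ec50_gamma_regression()].
#' @export
gen_microtox <- function(ec50_true, slope = 2,
                         dilutions = c(90.9, 45.45, 22.73, 11.36),
                         f_true = 0.9, i0_nominal = 1000, cv = 0,
                         replicates = 1, n_controls = 2, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  check_scalar_num(ec50_true, "ec50_true")
  if (ec50_true <= 0) abort("`ec50_true` must be > 0.")
  check_nonneg(cv, "cv")
  withr::with_seed(as.integer(seed), {
    noise <- function(n) if (cv > 0) exp(rnorm(n, 0, sqrt(log(1 + cv^2)))) else rep(1, n)
    rows <- purrr::map(seq_len(replicates), function(rep_id) {
      gamma <- (dilutions / ec50_true)^slope
      i0 <- i0_nominal * noise(length(dilutions))
      i15 <- f_true * i0 / (1 + gamma) * noise(length(dilutions))
      tibble::tibble(role = "sample", dilution_pct = dilutions,
                     i0 = i0, i15 = i15, replicate = rep_id)
    })
    ctl_i0 <- i0_nominal * noise(n_controls)
    controls <- tibble::tibble(role = "control", dilution_pct = NA_real_,
                               i0 = ctl_i0, i15 = f_true * ctl_i0,
                               replicate = NA_integer_)
    dplyr::bind_rows(dplyr::bind_rows(rows), controls)
  })
}

#' Generate paired before/after ASV tables with a dominance shift
#'
#' Emulates the community restructuring seen when a degrader consortium is
#' incubated with a toxicant: a "before" sample that is rich and fairly
#' even, and an "after" sample where one genus has swept to dominance.
#' Genus-level target proportions are fixed exactly; within each genus,
#' ASV-level proportions are Dirichlet-distributed, and reads are then
#' drawn multinomially at the requested (typically very unequal) depths.
#'
#' @param n_asv Total ASVs across the taxonomy (default 148).
#' @param n_genera Number of genera (default 12); ASVs are spread evenly.
#' @param dominant_genus Name of the sweeping genus (default
#'   `"Burkholderia"`).
#' @param dominant_prop Its target share in the "after" sample
#'   (default 0.889).
#' @param richness_before,richness_after Numbers of ASVs given positive
#'   probability in each sample (defaults 111 and 60). The "after" pool
#'   always contains every ASV of the dominant genus.
#' @param depths Named depths, default `c(before = 95729, after = 3231)`.
#' @param dirichlet_alpha Concentration of the within-genus Dirichlet
#'   (default 5; larger = more even ASVs within a genus).
#' @param seed Integer seed (mandatory).
#' @return A list with `counts` (2 x `n_asv` matrix, rows `before` and
#'   `after`) and `taxonomy` (tibble with `asv_id`, `genus`, and a QIIME2
#'   style `Taxon` lineage string).
#' @export
gen_asv_tables <- function(n_asv = 148, n_genera = 12,
                           dominant_genus = "Burkholderia",
                           dominant_prop = 0.889, richness_before = 111,
                           richness_after = 60,
                           depths = c(before = 95729, after = 3231),
                           dirichlet_alpha = 5, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  if (dominant_prop <= 0 || dominant_prop >= 1) {
    abort("`dominant_prop` must be in (0, 1).")
  }
  if (max(richness_before, richness_after) > n_asv) {
    abort("Richness targets cannot exceed `n_asv`.")
  }
  genera <- unique(c(dominant_genus,
                     c("Klebsiella", "Ochrobactrum", "Pseudomonas",
                       "Achromobacter", "Cupriavidus", "Stenotrophomonas",
                       "Rhizobium", "Sphingopyxis", "Enterobacter",
                       "Variovorax", "Acinetobacter",
                       paste0("Genus", seq_len(n_genera)))))[seq_len(n_genera)]
  asv_genus <- rep(genera, length.out = n_asv)
  asv_ids <- sprintf("ASV%03d", seq_len(n_asv))

  withr::with_seed(as.integer(seed), {
    # before: even genus targets; after: dominant genus at its target share
    before_genus <- setNames(rep(1 / n_genera, n_genera), genera)
    after_genus <- setNames(rep((1 - dominant_prop) / (n_genera - 1),
                                n_genera), genera)
    after_genus[dominant_genus] <- dominant_prop

    present_before <- seq_len(n_asv) %in%
      sample(seq_len(n_asv), richness_before)
    dom_idx <- which(asv_genus == dominant_genus)
    other_idx <- setdiff(seq_len(n_asv), dom_idx)
    n_extra <- max(richness_after - length(dom_idx), 0)
    present_after <- seq_len(n_asv) %in%
      c(dom_idx, sample(other_idx, min(n_extra, length(other_idx))))

    asv_props <- function(genus_targets, present) {
      p <- numeric(n_asv)
      for (g in genera) {
        idx <- which(asv_genus == g & present)
        if (length(idx) == 0) idx <- which(asv_genus == g)[1]
        w <- rgamma(length(idx), shape = dirichlet_alpha)
        p[idx] <- genus_targets[[g]] * w / sum(w)
      }
      p
    }
    p_before <- asv_props(before_genus, present_before)
    p_after <- asv_props(after_genus, present_after)
    counts <- rbind(
      before = as.vector(rmultinom(1, depths[["before"]], p_before)),
      after = as.vector(rmultinom(1, depths[["after"]], p_after))
    )
  })
  colnames(counts) <- asv_ids
  taxonomy <- tibble::tibble(
    asv_id = asv_ids, genus = asv_genus,
    Taxon = paste0("d__Bacteria; p__Pseudomonadota; c__; o__; f__; g__",
                   asv_genus)
  )
  list(counts = counts, taxonomy = taxonomy)
}
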