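#' Configuration of the synthetic qHTS + LD50 data generator
#'
#' Controls a generative model that emulates the screened data the package
#' consumes: per-compound latent potencies drive Hill-shaped cell-viability
#' loss curves across a cell-line panel (with baseline noise and isolated
#' spike artifacts to exercise the noise filter), a chemical-descriptor
#' matrix with a designated informative subset, and -log10 LD50 values that
#' load on both the chemical and the in vitro latent, so that hybrid
#' descriptors genuinely carry more signal than either space alone.
#'
#' Defaults reflect the screening setting modelled throughout the package:
#' 13 cell lines, a 14-point geometric concentration grid over
#' 0.006--92 uM, baseline noise of about 10 response percent, occasional
#' large isolated spikes, and a class mix of roughly one toxic to three
#' nontoxic among the non-marginal compounds.
#'
#' @param n_compounds Number of compounds.
#' @param n_chem_descriptors Total chemical descriptors.
#' @param n_informative_chem How many of them carry the chemical latent.
#' @param cell_lines Cell-line labels (defaults to the full 13-line panel).
#' @param grid Concentration grid (uM).
#' @param hill_slope_range Range of Hill slopes.
#' @param emax_range Range of maximal viability-loss responses (percent).
#' @param ac50_line_sd Per-cell-line jitter of log10 AC50 around the shared
#'   latent potency (log10 uM units).
#' @param assay_irrelevance Fraction of the shared in vitro potency
#'   variance that is unrelated to in vivo toxicity. Real cytotoxicity
#'   potency reflects membrane disruption, proliferation rate and other
#'   cell-level traits only partly linked to acute oral lethality --
#'   in vitro profiles alone are known to be weak classifiers of it -- so
#'   the potency latent mixes the toxicity-linked latent with an
#'   independent assay latent.
#' @param ac50_span_extension How far (log10 units) the AC50 distribution
#'   extends above the top assay concentration. Cytotoxicity screens are
#'   inactive-majority: a sizeable fraction of compounds never respond
#'   within the tested range, and their curves are pure baseline noise.
#'   The default (2) leaves roughly a third of compounds without a
#'   half-maximal response inside the grid.
#' @param baseline_noise_sd Gaussian per-point response noise (percent).
#' @param curve_shift_sd Per-curve baseline offset (percent): plate- or
#'   normalization-level shifts that displace a whole curve; the artifact
#'   class the baseline threshold (THR) exists to remove.
#' @param spike_probability Per-point probability of an isolated artifact.
#' @param spike_magnitude Artifact displacement (percent).
#' @param spike_negative_fraction Fraction of spikes directed toward
#'   apparent viability gain (negative on the toxicity scale). Transient
#'   screening artifacts -- dispense failures, luminescence bursts --
#'   predominantly mimic signal gain, producing the characteristic
#'   non-monotone dips the repair rule targets; the remainder point toward
#'   spurious viability loss.
#' @param chem_signal_weight,bio_signal_weight Loadings of the chemical and
#'   in vitro latents on -log10 LD50.
#' @param ld50_intercept Centre of the -log10 LD50 (mol/kg) distribution.
#' @param label_noise_sd Residual noise on -log10 LD50.
#' @param seed Integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_compounds = 400, n_chem_descriptors = 60,
                              n_informative_chem = 10,
                              cell_lines = qhts_cell_lines(),
                              grid = default_concentration_grid(),
                              hill_slope_range = c(1, 3),
                              emax_range = c(60, 100),
                              ac50_line_sd = 0.5,
                              ac50_span_extension = 2,
                              assay_irrelevance = 0.25,
                              baseline_noise_sd = 12,
                              curve_shift_sd = 8,
                              spike_probability = 0.15,
                              spike_magnitude = 60,
                              spike_negative_fraction = 0.8,
                              chem_signal_weight = 0.4,
                              bio_signal_weight = 0.4,
                              ld50_intercept = 2.2,
                              label_noise_sd = 0.4,
                              seed = 1) {
  stopifnot(spike_probability >= 0, spike_probability <= 1,
            all(diff(grid) > 0), chem_signal_weight >= 0,
            bio_signal_weight >= 0, n_informative_chem <= n_chem_descriptors)
  structure(as.list(environment()), class = "simulation_config")
}

#' Generate a synthetic qHTS + chemical-descriptor + LD50 dataset
#'
#' Draws per-compound chemical (`z_chem`) and in vitro (`z_bio`) latents;
#' `z_bio` sets a shared log10 AC50 spanning the concentration grid
#' (jittered per cell line), responses follow
#' `Emax * c^h / (AC50^h + c^h)` plus Gaussian baseline noise and isolated
#' spike artifacts; informative chemical descriptors load on `z_chem`
#' among correlated noise columns; and
#' `-log10 LD50 = intercept + w_chem * z_chem + w_bio * z_bio + noise`.
#' Ground truth (latents, AC50s, informative descriptor names) is returned
#' for recovery tests.
#'
#' @param config A [simulation_config()].
#' @return List with `profiles` ([qhts_profiles()]), `chem`
#'   (`descriptor_matrix`, unscaled), `tox` (data frame `compound_id`,
#'   `neg_log_ld50`, `tox_class`) and `truth` (list with `z_chem`, `z_bio`,
#'   `log_ac50` matrix, `emax`, `hill`, `informative`).
#' @export
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_compounds
    ids <- sprintf("CPD%04d", seq_len(n))
    nl <- length(cfg$cell_lines)
    ng <- length(cfg$grid)

    z_chem <- rnorm(n)
    z_bio <- rnorm(n)
    z_assay <- rnorm(n)  # in vitro potency variance unrelated to toxicity
    a <- cfg$assay_irrelevance
    z_potency <- sqrt(1 - a) * z_bio + sqrt(a) * z_assay

    lo <- log10(min(cfg$grid)); hi <- log10(max(cfg$grid))
    ext <- cfg$ac50_span_extension
    base_ac50 <- (hi + ext) - pnorm(z_potency) * (hi + ext - lo)
    log_ac50 <- base_ac50 + matrix(rnorm(n * nl, sd = cfg$ac50_line_sd), n, nl,
                                   dimnames = list(ids, cfg$cell_lines))
    emax <- matrix(runif(n * nl, cfg$emax_range[1L], cfg$emax_range[2L]),
                   n, nl, dimnames = list(ids, cfg$cell_lines))
    hill <- matrix(runif(n * nl, cfg$hill_slope_range[1L],
                         cfg$hill_slope_range[2L]), n, nl)

    resp <- matrix(0, n * nl, ng)
    comp <- rep(ids, each = nl)
    line <- rep(cfg$cell_lines, times = n)
    row <- 0L
    for (i in seq_len(n)) for (j in seq_len(nl)) {
      row <- row + 1L
      ac50 <- 10^log_ac50[i, j]
      h <- hill[i, j]
      mu <- emax[i, j] * cfg$grid^h / (ac50^h + cfg$grid^h)
      r <- mu + rnorm(1, sd = cfg$curve_shift_sd) +
        rnorm(ng, sd = cfg$baseline_noise_sd)
      spikes <- runif(ng) < cfg$spike_probability
      r[spikes] <- r[spikes] + cfg$spike_magnitude *
        sample(c(-1, 1), sum(spikes), replace = TRUE,
               prob = c(cfg$spike_negative_fraction,
                        1 - cfg$spike_negative_fraction))
      resp[row, ] <- r
    }
    profiles <- qhts_profiles(comp, line, resp, concentrations = cfg$grid,
                              panel = cfg$cell_lines)

    p <- cfg$n_chem_descriptors
    ninf <- cfg$n_informative_chem
    informative <- sprintf("chem_inf_%02d", seq_len(ninf))
    noise_names <- sprintf("chem_noise_%02d", seq_len(p - ninf))
    loadings <- runif(ninf, 0.7, 1.2)
    Xinf <- outer(z_chem, loadings) + matrix(rnorm(n * ninf, sd = 0.7), n, ninf)
    # correlated noise block: three shared latent factors
    fac <- matrix(rnorm(n * 3L), n, 3L)
    L <- matrix(runif((p - ninf) * 3L, -0.4, 0.4), p - ninf, 3L)
    Xnoise <- fac %*% t(L) + matrix(rnorm(n * (p - ninf)), n, p - ninf)
    chem <- cbind(Xinf, Xnoise)
    dimnames(chem) <- list(ids, c(informative, noise_names))
    chem <- descriptor_matrix(chem, origin = "chemical")

    neg_log_ld50 <- cfg$ld50_intercept + cfg$chem_signal_weight * z_chem +
      cfg$bio_signal_weight * z_bio + rnorm(n, sd = cfg$label_noise_sd)
    tox <- data.frame(compound_id = ids, neg_log_ld50 = neg_log_ld50,
                      tox_class = assign_toxicity_class(neg_log_ld50),
                      stringsAsFactors = FALSE)

    list(profiles = profiles, chem = chem, tox = tox,
         truth = list(z_chem = stats::setNames(z_chem, ids),
                      z_bio = stats::setNames(z_bio, ids),
                      z_potency = stats::setNames(z_potency, ids),
                      log_ac50 = log_ac50, emax = emax, hill = hill,
                      informative = informative))
  })
}

#' Deterministic worked-example curves
#'
#' Small hand-built 14-point fixtures used throughout the test suite:
#' * `fingerprint127` -- a filtered curve below 25% of scale at the ten
#'   lowest concentrations, in the 25--50% band at the 11th and above 75%
#'   at the three highest; its fingerprint integer is 127.
#' * `single_spike` -- a curve with one downward artifact between two valid
#'   points; the filter (THR 15, MXDV 5) repairs exactly that point by
#'   interpolation.
#' * `terminal_drop` -- a strong response collapsing at the highest
#'   concentrations; the filter extends the last valid value.
#' * `all_noise` -- baseline jitter only; the filter flattens it to zero.
#'
#' @return Named list of numeric response vectors (percent scale), with
#'   attribute `"notes"` describing each.
#' @export
generate_worked_examples <- function() {
  ex <- list(
    fingerprint127 = c(rep(5, 10), 30, 90, 90, 90),
    single_spike   = c(0, 0, 0, 0, 0, 0, 50, 10, 90, 95, 96, 97, 98, 99),
    terminal_drop  = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 80, 3, 2),
    all_noise      = c(3, -8, 12, -4, 7, -11, 9, -2, 13, -6, 4, -9, 11, -3))
  attr(ex, "notes") <- c(
    fingerprint127 = "quartile-bin pattern 00x10 01 11 11 11; integer 127",
    single_spike = "one monotonicity violation; repaired to 70 by interpolation",
    terminal_drop = "trailing baseline after a strong response; constant extension to 80",
    all_noise = "all |r| < 15; filtered curve is identically zero")
  ex
}
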