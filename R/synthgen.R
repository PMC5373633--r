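# Synthetic populations, images and flow-style event tables with known
# ground truth, used to validate every downstream stage of the pipeline.

# Log-normal draws parameterised by arithmetic mean and CV; cv = 0 collapses
# to the constant mean.
rlnorm_meancv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

with_opt_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Generate a ground-truth cell population
#'
#' Draws a population of cells with cell-cycle phases, DNA content and
#' nuclear replication signal. Each cell's phase is sampled independently
#' with the configured phase probabilities. The nuclear signal is the sum of
#' a specific component (replication-derived; nonzero only in S-phase cells)
#' and a non-specific background component present in every cell, both
#' log-normal. DNA content is `dna_g1` for G1, `2 * dna_g1` for G2/M, and
#' uniform in between for S-phase cells, each perturbed multiplicatively by
#' the measurement CV.
#'
#' @param pop A [population_params()] object.
#' @param cyc A [cell_cycle_params()] object; `cyc$frac_s` must equal
#'   `pop$frac_replicating`.
#' @return A `data.frame` (the population truth table) with columns
#'   `cell_id`, `phase` (`"G1"`, `"S"`, `"G2M"`), `dna_content`,
#'   `signal_specific`, `signal_background`, `true_signal`
#'   (`= signal_specific + signal_background`), and placement columns
#'   `center_row`, `center_col`, `radius` (`NA` until [render_images()]
#'   places the cells).
#' @examples
#' truth <- generate_population(population_params(n_cells = 500, seed = 1),
#'                              cell_cycle_params())
#' mean(truth$phase == "S")
#' @export
generate_population <- function(pop = population_params(),
                                cyc = cell_cycle_params()) {
  stopifnot(inherits(pop, "population_params"),
            inherits(cyc, "cell_cycle_params"))
  if (abs(pop$frac_replicating - cyc$frac_s) > 1e-9)
    stop("frac_replicating (", pop$frac_replicating,
         ") must equal the S-phase fraction frac_s (", cyc$frac_s,
         "): the replication signal is S-phase specific")
  n <- pop$n_cells
  with_opt_seed(pop$seed, {
    phase <- sample(c("G1", "S", "G2M"), n, replace = TRUE,
                    prob = c(cyc$frac_g1, cyc$frac_s, cyc$frac_g2m))
    is_s <- phase == "S"
    # Specific signal: mean chosen so the total S-phase mean is mu_signal_R.
    mu_spec <- pop$mu_signal_R - pop$mu_signal_nonR
    spec <- numeric(n)
    if (any(is_s) && mu_spec > 0)
      spec[is_s] <- rlnorm_meancv(sum(is_s), mu_spec, pop$cv_R)
    bg <- rlnorm_meancv(n, pop$mu_signal_nonR, pop$cv_nonR)

    dna_base <- numeric(n)
    dna_base[phase == "G1"] <- cyc$dna_g1
    dna_base[phase == "G2M"] <- cyc$dna_g2m
    dna_base[is_s] <- stats::runif(sum(is_s), cyc$dna_g1, cyc$dna_g2m)
    dna <- dna_base * rlnorm_meancv(n, 1, cyc$dna_cv)
    # Keep S-phase content strictly inside the 2N-4N interval so phase
    # membership stays recoverable from content alone.
    eps <- 1e-6 * cyc$dna_g1
    dna[is_s] <- pmin(pmax(dna[is_s], cyc$dna_g1 + eps), cyc$dna_g2m - eps)

    data.frame(cell_id = seq_len(n), phase = phase, dna_content = dna,
               signal_specific = spec, signal_background = bg,
               true_signal = spec + bg,
               center_row = rep(NA_real_, n), center_col = rep(NA_real_, n),
               radius = rep(NA_real_, n))
  })
}

# Rejection-sampling placement of non-overlapping disks.
place_cells <- function(n, img, max_attempts_per_cell = 2000) {
  rmin <- img$radius_range[1]; rmax <- img$radius_range[2]
  radius <- stats::runif(n, rmin, rmax)
  rows <- numeric(n); cols <- numeric(n)
  for (i in seq_len(n)) {
    r <- radius[i]
    placed <- FALSE
    for (a in seq_len(max_attempts_per_cell)) {
      cy <- stats::runif(1, r + 1, img$height - r)
      cx <- stats::runif(1, r + 1, img$width - r)
      if (i == 1L) { placed <- TRUE }
      else {
        j <- seq_len(i - 1L)
        d2 <- (rows[j] - cy)^2 + (cols[j] - cx)^2
        placed <- all(d2 >= (radius[j] + r + img$min_center_spacing)^2)
      }
      if (placed) { rows[i] <- cy; cols[i] <- cx; break }
    }
    if (!placed)
      stop("could not place all nuclei without overlap: placed ", i - 1L,
           " of ", n, " under the current spacing constraint")
  }
  data.frame(center_row = rows, center_col = cols, radius = radius)
}

#' Render synthetic two-channel microscopy images
#'
#' Renders each cell of a truth table as a disk. In the DAPI channel the
#' per-pixel intensity is `dapi_gain * dna_content / area`, so the integrated
#' nuclear DAPI intensity is proportional to DNA content; in the signal
#' channel every pixel inside the nucleus equals the cell's `true_signal`.
#' Optional Poisson shot noise and Gaussian read noise are applied, and
#' values are rounded and clipped to the configured bit depth. Cells lacking
#' placement columns are placed by rejection sampling under the
#' non-overlap/spacing constraint.
#'
#' @param truth A truth table from [generate_population()]. If `center_row`
#'   etc. are filled they are respected (and validated); otherwise cells are
#'   placed automatically.
#' @param img An [imaging_params()] object.
#' @return A list with integer matrices `dapi`, `signal` (intensities) and
#'   `labels` (pixel -> `cell_id`, 0 = background), plus `truth`, the input
#'   table with placement columns filled.
#' @export
render_images <- function(truth, img = imaging_params()) {
  stopifnot(is.data.frame(truth), inherits(img, "imaging_params"))
  n <- nrow(truth)
  h <- img$height; w <- img$width
  dapi <- matrix(0, h, w); sig <- matrix(0, h, w)
  labels <- matrix(0L, h, w)
  with_opt_seed(img$seed, {
    if (n > 0) {
      if (anyNA(truth$center_row)) {
        truth[, c("center_row", "center_col", "radius")] <- place_cells(n, img)
      } else {
        r <- truth$radius
        if (any(truth$center_row < r | truth$center_row > h - r + 1 |
                truth$center_col < r | truth$center_col > w - r + 1))
          stop("some cells do not fit within the image bounds at their radius")
      }
      for (i in seq_len(n)) {
        cy <- truth$center_row[i]; cx <- truth$center_col[i]
        r <- truth$radius[i]
        rr <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
        cc <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
        inside <- outer((rr - cy)^2, (cc - cx)^2, "+") <= r^2
        area <- sum(inside)
        dapi[rr, cc][inside] <- img$dapi_gain * truth$dna_content[i] / area
        sig[rr, cc][inside] <- truth$true_signal[i]
        labels[rr, cc][inside] <- truth$cell_id[i]
      }
    }
    if (img$poisson_noise) {
      dapi[] <- stats::rpois(length(dapi), dapi)
      sig[] <- stats::rpois(length(sig), sig)
    }
    if (img$gaussian_noise_sd > 0) {
      dapi <- dapi + stats::rnorm(length(dapi), 0, img$gaussian_noise_sd)
      sig <- sig + stats::rnorm(length(sig), 0, img$gaussian_noise_sd)
    }
  })
  top <- 2^img$bit_depth - 1
  clip <- function(x) { x <- round(x); x[x < 0] <- 0; x[x > top] <- top
                        storage.mode(x) <- "integer"; x }
  list(dapi = clip(dapi), signal = clip(sig), labels = labels, truth = truth)
}

#' Generate a flow-style event table from a truth population
#'
#' One event per cell: the true nuclear signal and DNA content, each
#' perturbed by independent multiplicative log-normal measurement noise with
#' the given CV, in randomised acquisition order.
#'
#' @param truth A truth table from [generate_population()].
#' @param noise_cv Measurement coefficient of variation (>= 0; 0 reproduces
#'   the truth columns exactly).
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `event_id` (acquisition order),
#'   `cell_id`, `signal`, `dna_content`.
#' @export
generate_flow_events <- function(truth, noise_cv = 0.05, seed = NULL) {
  stopifnot(is.data.frame(truth), noise_cv >= 0)
  n <- nrow(truth)
  with_opt_seed(seed, {
    ord <- sample.int(n)
    data.frame(event_id = seq_len(n),
               cell_id = truth$cell_id[ord],
               signal = truth$true_signal[ord] * rlnorm_meancv(n, 1, noise_cv),
               dna_content = truth$dna_content[ord] *
                 rlnorm_meancv(n, 1, noise_cv))
  })
}

#' Apply antibody dissociation or stabilisation to a population
#'
#' Models what post-antibody washing does to the nuclear signal. Without
#' stabilisation, the specifically bound component decays first-order, being
#' multiplied by [retained_fraction()] at the wash duration; with
#' formaldehyde stabilisation the complex is cross-linked at the start of the
#' wash, so the specific component is instead multiplied by the
#' concentration-dependent [stabilisation_factor()] and does not decay
#' further. The non-specific background component is unchanged in either
#' case.
#'
#' @param truth A truth table from [generate_population()].
#' @param kin An [antibody_kinetics()] object.
#' @param t_wash Wash duration in minutes (>= 0).
#' @param stabilised If `TRUE`, formaldehyde post-fixation is applied.
#' @param formaldehyde_conc Formaldehyde concentration (percent, >= 0); only
#'   used when `stabilised = TRUE`.
#' @return The truth table with `signal_specific` and `true_signal` updated.
#' @export
apply_wash_dissociation <- function(truth, kin = antibody_kinetics(),
                                    t_wash, stabilised = FALSE,
                                    formaldehyde_conc = 0.2) {
  stopifnot(is.data.frame(truth), inherits(kin, "antibody_kinetics"))
  if (t_wash < 0) stop("t_wash must be >= 0 minutes")
  if (formaldehyde_conc < 0) stop("formaldehyde_conc must be >= 0 percent")
  factor <- if (stabilised)
    stabilisation_factor(formaldehyde_conc, kin)
  else
    retained_fraction(kin$k_off, t_wash)
  truth$signal_specific <- truth$signal_specific * factor
  truth$true_signal <- truth$signal_specific + truth$signal_background
  truth
}
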