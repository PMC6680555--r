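#' Build the FT-MIR and NIR wavenumber grids
#'
#' The FT-MIR grid spans exactly the two analytically useful segments
#' 3700-2620 and 1800-650 cm^-1 (the baseline region 4000-3700 and the
#' diamond/ATR crystal region 2620-1800 are never generated); points are
#' allocated to the two segments proportionally to their width. The NIR
#' grid spans 10000-4000 cm^-1 evenly. Both grids are descending.
#'
#' @param ftmir_n,nir_n Number of grid points (defaults 1150 and 1545,
#'   the study dimensionality).
#' @return List with elements `ftmir` and `nir`.
#' @export
make_grids <- function(ftmir_n = 1150, nir_n = 1545) {
  if (ftmir_n < 4 || nir_n < 2) stop("grids need at least 4 (FT-MIR) / 2 (NIR) points")
  seg1 <- c(3700, 2620)
  seg2 <- c(1800, 650)
  w1 <- diff(rev(seg1)); w2 <- diff(rev(seg2))
  n1 <- max(2L, round(ftmir_n * w1 / (w1 + w2)))
  n2 <- ftmir_n - n1
  ftmir <- c(seq(seg1[1], seg1[2], length.out = n1),
             seq(seg2[1], seg2[2], length.out = n2))
  nir <- seq(10000, 4000, length.out = nir_n)
  list(ftmir = ftmir, nir = nir)
}

# Common-backbone peaks shared by all classes. Centers follow the bands a
# powdered-rhizome spectrum shows (O-H/C-H stretches, carbonyl, carbohydrate
# fingerprint; NIR overtone/combination bands); heights/widths are plausible
# absorbance-scale values, not fitted to any instrument.
backbone_peaks <- function() {
  ftmir <- data.frame(
    modality = "FTMIR",
    center = c(3382, 3334, 2930, 1743, 1653, 1610, 1456, 1414, 1370,
               1242, 1150, 1078, 1020, 922),
    height = c(0.85, 0.80, 0.55, 0.28, 0.50, 0.44, 0.30, 0.28, 0.25,
               0.34, 0.50, 0.56, 0.62, 0.30),
    width  = c(120, 110, 42, 24, 30, 26, 20, 18, 16, 22, 26, 26, 26, 18))
  nir <- data.frame(
    modality = "NIR",
    center = c(8347, 7256, 6950, 6324, 5686, 5169, 4750, 4350),
    height = c(0.14, 0.20, 0.24, 0.30, 0.42, 0.60, 0.50, 0.55),
    width  = c(260, 230, 210, 220, 190, 160, 130, 110))
  rbind(ftmir, nir)
}

#' Noise model for synthetic spectra
#'
#' @param additive_sd Standard deviation of iid Gaussian noise per point.
#' @param baseline_amplitude Coefficients of a per-sample quadratic baseline
#'   are drawn from `U(-baseline_amplitude, baseline_amplitude)`.
#' @param scatter_gain,scatter_offset Ranges of the per-sample multiplicative
#'   scatter `y' = a*y + b`, with `a ~ U(scatter_gain)` and
#'   `b ~ U(scatter_offset)`; SNV is the exact inverse of this corruption.
#' @param height_jitter_sd Relative per-sample, per-peak height jitter
#'   (`h -> h * (1 + N(0, sd))`), emulating natural composition variability
#'   between samples; this is what gives real spectra their dominant smooth
#'   covariance structure.
#' @param baseline_degree Degree of the per-sample baseline polynomial
#'   (default 2; higher degrees emulate drift whose shape changes from
#'   sample to sample).
#' @return List of class `noise_model`.
#' @export
noise_model <- function(additive_sd = 0.005, baseline_amplitude = 0.03,
                        scatter_gain = c(0.9, 1.1),
                        scatter_offset = c(-0.02, 0.02),
                        height_jitter_sd = 0.03, baseline_degree = 2) {
  stopifnot(additive_sd >= 0, baseline_amplitude >= 0,
            length(scatter_gain) == 2, length(scatter_offset) == 2,
            height_jitter_sd >= 0, baseline_degree >= 0)
  structure(list(additive_sd = additive_sd,
                 baseline_amplitude = baseline_amplitude,
                 scatter_gain = sort(scatter_gain),
                 scatter_offset = sort(scatter_offset),
                 height_jitter_sd = height_jitter_sd,
                 baseline_degree = as.integer(baseline_degree)),
            class = "noise_model")
}

#' Per-class peak profiles
#'
#' A class profile is the fully materialised peak table (center, height,
#' width per modality) for one class: the shared backbone with small
#' class-specific height multipliers (5-20%) and center shifts (<= 4 cm^-1)
#' applied to a designated subset of discriminative peaks.
#'
#' @param n_classes Number of classes (default 5).
#' @return List of `n_classes` profiles, each
#'   `list(class_id, peaks = data.frame(modality, center, height, width))`.
#' @export
default_class_profiles <- function(n_classes = 5) {
  stopifnot(n_classes >= 2, n_classes <= 5)
  base <- backbone_peaks()
  # discriminative peaks and the per-class adjustment tables
  mir_disc <- c(1653, 1242, 1078)
  mir_mult <- rbind(c(1.15, 0.90, 1.05),
                    c(0.90, 1.12, 0.95),
                    c(1.05, 1.05, 1.15),
                    c(0.85, 0.95, 0.90),
                    c(1.10, 1.15, 0.85))
  mir_shift <- cbind(c(-3, -1, 0, 1, 3), 0, 0)  # shift on 1653 only
  nir_disc <- c(6324, 5169, 4750)
  nir_mult <- rbind(c(1.10, 0.92, 1.00),
                    c(0.90, 1.10, 1.08),
                    c(1.12, 1.00, 0.90),
                    c(0.95, 1.15, 1.12),
                    c(1.05, 0.88, 0.95))
  nir_shift <- cbind(0, c(2, -2, 0, 3, -3), 0)  # shift on 5169 only
  lapply(seq_len(n_classes), function(k) {
    pk <- base
    i <- match(mir_disc, pk$center)
    pk$height[i] <- pk$height[i] * mir_mult[k, ]
    pk$center[i] <- pk$center[i] + mir_shift[k, ]
    j <- match(nir_disc, pk$center)
    pk$height[j] <- pk$height[j] * nir_mult[k, ]
    pk$center[j] <- pk$center[j] + nir_shift[k, ]
    list(class_id = k, peaks = pk)
  })
}

gaussian_signal <- function(grid, peaks) {
  y <- numeric(length(grid))
  for (i in seq_len(nrow(peaks)))
    y <- y + peaks$height[i] *
      exp(-0.5 * ((grid - peaks$center[i]) / peaks$width[i])^2)
  y
}

simulate_one_modality <- function(grid, modality, n_per_class, profiles,
                                  noise, seed) {
  K <- length(profiles)
  span <- range(grid)
  n <- sum(n_per_class)
  labels <- rep(seq_len(K), times = n_per_class)
  X <- matrix(0, n, length(grid))
  jit <- noise$height_jitter_sd %||% 0
  with_substream(seed, paste0("simulate-", modality), {
    u <- (grid - span[1]) / (span[2] - span[1])
    row <- 0
    for (k in seq_len(K)) {
      pk <- profiles[[k]]$peaks
      pk <- pk[pk$modality == modality, , drop = FALSE]
      if (nrow(pk) == 0) stop("profile for class ", k, " has no ", modality, " peaks")
      if (any(pk$center < min(grid) | pk$center > max(grid)))
        stop("peak center outside the ", modality, " grid span for class ", k)
      if (any(pk$height <= 0) || any(pk$width <= 0))
        stop("peak heights and widths must be positive")
      # peak basis: one unit-height Gaussian per row
      G <- t(vapply(seq_len(nrow(pk)), function(i)
        exp(-0.5 * ((grid - pk$center[i]) / pk$width[i])^2),
        numeric(length(grid))))
      for (s in seq_len(n_per_class[k])) {
        row <- row + 1
        h <- pk$height * (1 + stats::rnorm(nrow(pk), 0, jit))
        sig <- as.numeric(h %*% G)
        deg <- noise$baseline_degree %||% 2L
        cf <- stats::runif(deg + 1, -noise$baseline_amplitude,
                           noise$baseline_amplitude)
        baseline <- as.numeric(outer(u, 0:deg, `^`) %*% cf)
        a <- stats::runif(1, noise$scatter_gain[1], noise$scatter_gain[2])
        b <- stats::runif(1, noise$scatter_offset[1], noise$scatter_offset[2])
        X[row, ] <- a * (sig + baseline) + b +
          stats::rnorm(length(grid), 0, noise$additive_sd)
      }
    }
  })
  list(X = X, labels = labels)
}

#' Simulate paired FT-MIR and NIR blocks
#'
#' Each spectrum is the class's Gaussian-peak signal plus a per-sample
#' quadratic baseline, an affine scatter corruption `a*y + b`, and iid
#' Gaussian noise. The two blocks are row-aligned (same sample ids and
#' labels); the default class sizes (40, 40, 36, 40, 40) give the study's
#' n = 196.
#'
#' @param n_per_class Integer vector of class sizes.
#' @param profiles Output of [default_class_profiles()] (or compatible).
#' @param noise A [noise_model()].
#' @param seed Integer master seed; all randomness derives from it.
#' @param grids Output of [make_grids()].
#' @return List with [spectral_block()] elements `ftmir` and `nir`.
#' @export
simulate_blocks <- function(n_per_class = c(40, 40, 36, 40, 40),
                            profiles = default_class_profiles(length(n_per_class)),
                            noise = noise_model(), seed = 1,
                            grids = make_grids()) {
  if (length(profiles) != length(n_per_class))
    stop("length(profiles) != length(n_per_class)")
  if (any(n_per_class < 1)) stop("empty class")
  ids <- sprintf("S%03d", seq_len(sum(n_per_class)))
  fm <- simulate_one_modality(grids$ftmir, "FTMIR", n_per_class, profiles, noise, seed)
  nr <- simulate_one_modality(grids$nir, "NIR", n_per_class, profiles, noise, seed)
  list(ftmir = spectral_block("FTMIR", grids$ftmir, fm$X, ids, fm$labels),
       nir = spectral_block("NIR", grids$nir, nr$X, ids, nr$labels))
}

# Marker-band layout of the complementary scenario. Marker bands are
# narrower than one grid step and snapped onto grid points, so each marker
# occupies a single column and the truly discriminative support is exactly
# six columns per block. Centers sit in low-backbone windows so composition
# jitter of the backbone does not mask the class contrast. Each marker
# carries one distinct class contrast, so none is redundant.
complementary_markers <- function() {
  mir_centers <- c(3650, 3080, 2750, 1335, 860, 700)
  nir_centers <- c(9700, 9400, 9100, 8800, 7800, 4050)
  # Rows = markers, columns = classes 1..5. FT-MIR markers resolve the
  # pairs within classes 1-3 and the {1,2,3} vs {4,5} group; classes 4-5
  # differ by at most 1% (weak). NIR is the converse: class 4 vs 5 and the
  # group are strong, the trio contrasts are weak echoes.
  mir_pat <- rbind(c(1.08, 0.92, 1.00, 1.00, 1.00),
                   c(1.08, 1.00, 0.92, 1.00, 1.00),
                   c(1.00, 1.08, 0.92, 1.00, 1.00),
                   c(1.06, 1.05, 1.07, 0.95, 0.94),
                   c(0.94, 0.95, 0.93, 1.05, 1.06),
                   c(1.06, 0.94, 1.06, 1.00, 1.00))
  nir_pat <- rbind(c(1.00, 1.00, 1.00, 1.08, 0.92),
                   c(0.95, 0.96, 0.94, 1.05, 1.06),
                   c(1.06, 1.05, 1.07, 0.95, 0.94),
                   c(0.99, 1.00, 1.01, 1.06, 1.00),
                   c(1.01, 0.99, 1.00, 1.00, 1.06),
                   c(1.00, 1.01, 0.99, 0.95, 1.05))
  list(mir = data.frame(center = mir_centers, height = 0.30, width = 1.5),
       nir = data.frame(center = nir_centers, height = 0.30, width = 2.8),
       mir_pat = mir_pat, nir_pat = nir_pat)
}

#' Complementary two-block scenario with known discriminative variables
#'
#' Builds paired blocks in which FT-MIR separates classes 1-3 strongly but
#' classes 4-5 only marginally, and NIR the converse, so neither block alone
#' can resolve all five classes while their fusion can (by construction the
#' single-block Bayes accuracy is below the fused Bayes accuracy). Narrow
#' class-dependent marker bands, one grid column each, carry all
#' discriminative signal; the returned masks flag the columns inside the
#' marker supports (|wavenumber - center| <= width), the scenario's ground
#' truth for selection-recovery checks. The full noise model applies
#' (composition jitter, scatter, baseline, additive noise), so spectra keep
#' the dominant smooth covariance of real data; marker centers sit in
#' low-backbone windows so the masks stay exact under that nuisance
#' structure. SNV removes the affine scatter before modelling.
#'
#' @param seed Integer master seed.
#' @param n_per_class Class sizes (default the study's 40, 40, 36, 40, 40).
#' @param additive_sd Per-point noise sd (default 0.002, the scale of
#'   instrument noise relative to natural composition variability).
#' @return List: `ftmir`, `nir` ([spectral_block()]s), `mask_ftmir`,
#'   `mask_nir` (logical, TRUE at truly discriminative columns).
#' @export
make_complementary_scenario <- function(seed = 1,
                                        n_per_class = c(40, 40, 36, 40, 40),
                                        additive_sd = 0.002) {
  mk <- complementary_markers()
  K <- length(n_per_class)
  stopifnot(K == 5)
  grids <- make_grids()
  # snap marker centers onto the grid so each band sits on one column
  snap <- function(tab, grid) {
    tab$center <- vapply(tab$center,
                         function(cc) grid[which.min(abs(grid - cc))],
                         numeric(1))
    tab
  }
  mk$mir <- snap(mk$mir, grids$ftmir)
  mk$nir <- snap(mk$nir, grids$nir)
  base <- backbone_peaks()
  profiles <- lapply(seq_len(K), function(k) {
    mir <- transform(mk$mir, modality = "FTMIR", height = height * mk$mir_pat[, k])
    nir <- transform(mk$nir, modality = "NIR", height = height * mk$nir_pat[, k])
    list(class_id = k,
         peaks = rbind(base, mir[names(base)], nir[names(base)]))
  })
  noise <- noise_model(additive_sd = additive_sd, baseline_amplitude = 0.01)
  blocks <- simulate_blocks(n_per_class, profiles, noise, seed, grids)
  in_support <- function(grid, tab)
    Reduce(`|`, lapply(seq_len(nrow(tab)), function(i)
      abs(grid - tab$center[i]) <= tab$width[i]))
  list(ftmir = blocks$ftmir, nir = blocks$nir,
       mask_ftmir = in_support(blocks$ftmir$grid, mk$mir),
       mask_nir = in_support(blocks$nir$grid, mk$nir))
}
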