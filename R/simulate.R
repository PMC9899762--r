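#' Synthetic inputs for the colocalization and molecular stages
#'
#' These generators emulate the remaining study inputs -- two-channel
#' confocal volumes, qPCR CT tables, immunoblot lane measurements, and
#' six-segment SAH grade sheets -- with known ground truth, so every
#' downstream computation can be verified end to end.
#'
#' @name simulate
NULL

# FFT Gaussian smoothing with periodic boundaries (adequate for synthetic
# fields; no edge artifacts matter here).
gauss_smooth_3d <- function(x, sigma) {
  d <- dim(x)
  k1 <- function(n, s) {
    i <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    g <- exp(-i^2 / (2 * s^2))
    g / sum(g)
  }
  K <- outer(outer(k1(d[1], sigma[1]), k1(d[2], sigma[2])), k1(d[3], sigma[3]))
  dim(K) <- d
  Re(fft(fft(x) * fft(K), inverse = TRUE)) / prod(d)
}

standardize <- function(x) (x - mean(x)) / stats::sd(x)

# Sparse blob field: Poisson points smoothed into Gaussian spots
# (unnormalized, so spot count and amplitude control mass and variance).
# Spots are made compactly supported by zeroing the faint smoothing tails,
# so the inter-spot background is exactly empty.
blob_field <- function(d, n_blobs, sigma, amplitude = 1, avoid = NULL) {
  x <- array(0, d)
  n <- max(1L, stats::rpois(1, n_blobs))
  placed <- 0L
  guard <- 0L
  while (placed < n && guard < 50L * n) {
    guard <- guard + 1L
    i <- cbind(sample.int(d[1], 1), sample.int(d[2], 1), sample.int(d[3], 1))
    # keep spot centers off another field's support when disjoint channels
    # are requested
    if (!is.null(avoid) && avoid[i] > 0) next
    x[i] <- amplitude * stats::runif(1, 0.75, 1.25)
    placed <- placed + 1L
  }
  f <- gauss_smooth_3d(x, sigma)
  f[f < 0.08 * max(f)] <- 0
  f
}

#' A two-channel intensity volume
#'
#' @param channel_a,channel_b non-negative 3-D arrays of identical shape.
#' @param voxel_size length-3 micrometre voxel size (x, y, z).
#' @return object of class `"volume_pair"`.
#' @export
volume_pair <- function(channel_a, channel_b, voxel_size = c(0.414, 0.414, 0.2)) {
  stopifnot(is.array(channel_a), is.array(channel_b),
            length(dim(channel_a)) == 3,
            identical(dim(channel_a), dim(channel_b)),
            all(voxel_size > 0))
  if (any(!is.finite(channel_a)) || any(!is.finite(channel_b)) ||
      min(channel_a) < 0 || min(channel_b) < 0) {
    stop("channel intensities must be finite and non-negative", call. = FALSE)
  }
  structure(list(channel_a = channel_a, channel_b = channel_b,
                 voxel_size = voxel_size),
            class = "volume_pair")
}

#' Simulate a correlated two-channel volume
#'
#' Two generator styles share one principle: each channel mixes a common
#' structured component with channel-specific components, in proportions
#' solved from the requested statistics.
#'
#' * `style = "gaussian"`: components are smoothed, standardized Gaussian
#'   fields mixed as `a = sqrt(|rho|) S + sqrt(1 - |rho| - nu^2) N_a + nu E_a`
#'   (and `-S` for negative `rho`), then shifted to non-negative, so the
#'   expected Pearson coefficient equals `rho` exactly. An unattainable
#'   combination (`noise_frac^2 > 1 - |rho|`) errors.
#' * `style = "blobs"`: channels are sparse, compactly supported Gaussian
#'   spot fields sharing a fraction `coloc_fraction` of their spot mass
#'   (the generating truth for percent material colocalized), over an
#'   independent noise floor. When `rho` is also requested, the common
#'   spots are made brighter but fewer, keeping the mass share at
#'   `coloc_fraction` while setting the common-variance share (hence the
#'   whole-stack correlation of the disjoint spot mixture) to `rho`; both
#'   targets are then approximate.
#'
#' @param shape length-3 voxel dimensions.
#' @param rho target Pearson coefficient in `[-1, 1]` (`NULL` to leave the
#'   blob mixture's correlation as it falls).
#' @param coloc_fraction fraction of blob mass shared between channels
#'   (blob style only).
#' @param style `"gaussian"` or `"blobs"`.
#' @param blur_sigma smoothing width in voxels.
#' @param noise_frac standard-deviation fraction of unstructured voxel
#'   noise, relative to the peak intensity (default 0.05 for gaussian
#'   style, 0.01 for blobs).
#' @param n_blobs expected spot count per component field (blob style).
#' @param voxel_size micrometres per voxel.
#' @param seed integer seed.
#' @return a [volume_pair()] with attribute `"truth"` recording the
#'   generating parameters.
#' @export
make_coloc_volume <- function(shape = c(64, 64, 16), rho = NULL,
                              coloc_fraction = NULL,
                              style = c("gaussian", "blobs"),
                              blur_sigma = 1.2, noise_frac = NULL,
                              n_blobs = 60, voxel_size = c(0.414, 0.414, 0.2),
                              seed = 1L) {
  style <- match.arg(style)
  stopifnot(length(shape) == 3, all(shape >= 4))
  if (!is.null(rho) && (rho < -1 || rho > 1)) stop("rho must be in [-1, 1]", call. = FALSE)
  sig <- rep(blur_sigma, length.out = 3)
  if (is.null(noise_frac)) noise_frac <- if (style == "gaussian") 0.05 else 0.01
  with_subseed(seed, {
    if (style == "gaussian") {
      if (is.null(rho)) stop("gaussian style needs a target rho", call. = FALSE)
      ar <- abs(rho)
      if (noise_frac^2 > 1 - ar + 1e-12) {
        stop(sprintf("rho = %.2f unattainable with noise_frac = %.2f", rho, noise_frac),
             call. = FALSE)
      }
      S <- standardize(gauss_smooth_3d(array(stats::rnorm(prod(shape)), shape), sig))
      Na <- standardize(gauss_smooth_3d(array(stats::rnorm(prod(shape)), shape), sig))
      Nb <- standardize(gauss_smooth_3d(array(stats::rnorm(prod(shape)), shape), sig))
      beta <- sqrt(max(1 - ar - noise_frac^2, 0))
      a <- sqrt(ar) * S + beta * Na + noise_frac * array(stats::rnorm(prod(shape)), shape)
      b <- sign(rho + (rho == 0)) * sqrt(ar) * S + beta * Nb +
        noise_frac * array(stats::rnorm(prod(shape)), shape)
      a <- a - min(a); b <- b - min(b)
    } else {
      f <- if (is.null(coloc_fraction)) 0.5 else coloc_fraction
      stopifnot(f >= 0, f <= 1)
      if (f == 0 || f == 1) {
        if (!is.null(rho)) {
          stop("rho cannot be targeted when coloc_fraction is 0 or 1", call. = FALSE)
        }
        if (f == 1) {
          a <- blob_field(shape, n_blobs, sig)
          b <- a
        } else {
          # disjoint channels: the second field's spots avoid the first
          # field's support, so the non-overlap is known by construction
          a <- blob_field(shape, n_blobs, sig)
          b <- blob_field(shape, n_blobs, sig, avoid = a)
        }
      } else {
        # common spots carry fraction f of each channel's mass; when a
        # correlation target is also given, the common spots are made
        # brighter but fewer (mass share fixed at f, variance share at
        # rho), since the whole-stack PCC of disjoint spot fields is their
        # common-variance share
        mass_ratio <- f / (1 - f)
        if (!is.null(rho)) {
          if (rho <= 0 || rho >= 1) {
            stop("blob style needs rho strictly inside (0, 1)", call. = FALSE)
          }
          amp_c <- (rho / (1 - rho)) / mass_ratio
          n_c <- n_blobs * mass_ratio^2 * (1 - rho) / rho
        } else {
          amp_c <- 1
          n_c <- n_blobs * mass_ratio
        }
        if (n_c < 1) stop("target rho unattainable: no common spots left", call. = FALSE)
        C <- blob_field(shape, n_c, sig, amplitude = amp_c)
        a <- C + blob_field(shape, n_blobs, sig)
        b <- C + blob_field(shape, n_blobs, sig)
      }
      # independent noise floor (folded normal, so every voxel carries some
      # independent signal): decorrelates the sub-threshold population,
      # which is what lets the automatic threshold scan terminate
      if (noise_frac > 0) {
        sd_n <- noise_frac * max(a, b)
        a <- a + abs(array(stats::rnorm(prod(shape), 0, sd_n), shape))
        b <- b + abs(array(stats::rnorm(prod(shape), 0, sd_n), shape))
      }
      mx <- max(a, b, 1e-12)
      a <- pmax(a, 0) / mx; b <- pmax(b, 0) / mx
      dim(a) <- shape; dim(b) <- shape
    }
    vp <- volume_pair(a, b, voxel_size)
    attr(vp, "truth") <- list(style = style, rho = rho,
                              coloc_fraction = coloc_fraction, seed = seed)
    vp
  })
}

#' Simulate a qPCR CT table
#'
#' CT values follow the Livak model: every sample gets a random
#' RNA-loading shift common to all its genes, the reference gene sits at
#' `base_ct` plus that shift, and each target gene sits `dct` cycles above
#' the reference, where the group's fold effect lowers `dct` by
#' `log2(fold)`. With `noise_sd = 0` the generated fold changes are
#' recovered exactly by [ddct_fold_changes()].
#'
#' @param genes character vector of target gene names.
#' @param effects tibble with columns `gene`, `group`, `fold` giving the
#'   true expression fold change versus the control group (unlisted
#'   combinations default to 1).
#' @param n_per_group named integer vector of sample counts per group (or a
#'   single count recycled over `groups`).
#' @param groups group labels; the first is the control.
#' @param base_dct named baseline delta-CT per gene (default 3 cycles above
#'   the reference for every gene).
#' @param base_ct reference-gene CT level.
#' @param load_sd standard deviation of the per-sample loading shift.
#' @param noise_sd per-well CT measurement noise.
#' @param reference_gene reference gene name.
#' @param seed integer seed.
#' @return tibble with columns `sample`, `group`, `gene`, `ct` plus
#'   attributes `reference_gene` and `control_group`.
#' @export
make_ct_table <- function(genes, effects = NULL, n_per_group = 6L,
                          groups = c("SHAM", "SAH", "SAH+Mino"),
                          base_dct = NULL, base_ct = 18,
                          load_sd = 0.4, noise_sd = 0.2,
                          reference_gene = "GAPDH", seed = 1L) {
  if (length(n_per_group) == 1) {
    n_per_group <- stats::setNames(rep(n_per_group, length(groups)), groups)
  }
  if (is.null(base_dct)) base_dct <- stats::setNames(rep(3, length(genes)), genes)
  if (sum(n_per_group) == 0) {
    return(structure(tibble::tibble(sample = character(), group = character(),
                                    gene = character(), ct = numeric()),
                     reference_gene = reference_gene, control_group = groups[1]))
  }
  fold_of <- function(gene, group) {
    if (is.null(effects)) return(1)
    hit <- effects$fold[effects$gene == gene & effects$group == group]
    if (length(hit) == 0) 1 else hit[1]
  }
  with_subseed(seed, {
    rows <- list()
    for (g in groups) {
      for (i in seq_len(n_per_group[[g]])) {
        sid <- sprintf("%s_%02d", g, i)
        shift <- stats::rnorm(1, 0, load_sd)
        ct_ref <- base_ct + shift + stats::rnorm(1, 0, noise_sd)
        rows[[length(rows) + 1]] <- tibble::tibble(
          sample = sid, group = g, gene = reference_gene, ct = ct_ref)
        for (gene in genes) {
          dct <- base_dct[[gene]] - log2(fold_of(gene, g))
          rows[[length(rows) + 1]] <- tibble::tibble(
            sample = sid, group = g, gene = gene,
            ct = ct_ref + dct + stats::rnorm(1, 0, noise_sd))
        }
      }
    }
    structure(dplyr::bind_rows(rows),
              reference_gene = reference_gene, control_group = groups[1])
  })
}

#' Simulate six-segment SAH grade sheets
#'
#' The basal brain is divided into six segments, each graded 0-3 by the
#' amount of subarachnoid blood; the sheet total (0-18) is the animal's SAH
#' grade.
#'
#' @param n number of animals.
#' @param prob length-4 probability vector over grades 0:3, or one of the
#'   presets `"sah"` (blood-heavy), `"sham"` (all zeros), `"all3"`
#'   (maximal).
#' @param seed integer seed.
#' @return tibble with columns `animal`, `seg1`..`seg6`.
#' @export
make_grade_sheet <- function(n, prob = "sah", seed = 1L) {
  if (is.character(prob)) {
    prob <- switch(match.arg(prob, c("sah", "sham", "all3")),
                   sah = c(0.05, 0.2, 0.4, 0.35),
                   sham = c(1, 0, 0, 0),
                   all3 = c(0, 0, 0, 1))
  }
  stopifnot(length(prob) == 4, all(prob >= 0), sum(prob) > 0)
  if (n == 0) {
    return(tibble::tibble(animal = character(),
                          seg1 = integer(), seg2 = integer(), seg3 = integer(),
                          seg4 = integer(), seg5 = integer(), seg6 = integer()))
  }
  with_subseed(seed, {
    g <- matrix(sample(0:3, 6 * n, replace = TRUE, prob = prob), n, 6)
    out <- tibble::tibble(animal = sprintf("r%02d", seq_len(n)))
    for (j in 1:6) out[[paste0("seg", j)]] <- as.integer(g[, j])
    out
  })
}

#' Simulate immunoblot densitometry lanes
#'
#' Each membrane carries its own multiplicative gain (scanner exposure) and
#' background level; every sample's true normalized protein level is its
#' group fold effect. With `noise_sd = 0`, [blot_fold_changes()] recovers
#' the generating folds exactly and identically across membranes.
#'
#' @param group_folds named numeric vector of true fold change per group
#'   (control group must be 1).
#' @param n_per_group samples per group on each membrane.
#' @param n_membranes number of membranes; every membrane carries all
#'   groups.
#' @param control_group name of the control group.
#' @param loading mean loading-control band intensity.
#' @param background mean membrane background level.
#' @param gains per-membrane multiplicative gains (recycled).
#' @param noise_sd relative intensity noise.
#' @param seed integer seed.
#' @return tibble with columns `membrane`, `sample`, `group`, `band`,
#'   `background_above`, `background_below`, `loading`.
#' @export
make_lane_table <- function(group_folds = c(SHAM = 1, SAH = 1.8, `SAH+Mino` = 1.2),
                            n_per_group = 4L, n_membranes = 2L,
                            control_group = names(group_folds)[1],
                            loading = 500, background = 100,
                            gains = c(1, 1.6), noise_sd = 0, seed = 1L) {
  gains <- rep(gains, length.out = n_membranes)
  with_subseed(seed, {
    rows <- list()
    for (m in seq_len(n_membranes)) {
      gn <- gains[m]
      for (g in names(group_folds)) {
        for (i in seq_len(n_per_group)) {
          lane_load <- loading * exp(stats::rnorm(1, 0, noise_sd))
          level <- group_folds[[g]] * exp(stats::rnorm(1, 0, noise_sd))
          bg <- background * gn
          rows[[length(rows) + 1]] <- tibble::tibble(
            membrane = sprintf("m%d", m),
            sample = sprintf("m%d_%s_%02d", m, g, i), group = g,
            band = (level * lane_load) * gn + bg,
            background_above = bg, background_below = bg,
            loading = lane_load * gn)
        }
      }
    }
    structure(dplyr::bind_rows(rows), control_group = control_group)
  })
}
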