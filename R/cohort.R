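SEQUENCE_SPACINGS <- list(
  T2 = c(0.33, 0.33, 3.00),
  DWI_b800 = c(1.21, 1.21, 4.00),
  T1_pre = c(1, 1, 1),
  T1_initial = c(1, 1, 1),
  T1_delayed = c(1, 1, 1))

SEQUENCE_CONTRAST <- c(T2 = 60, DWI_b800 = 50, T1_pre = 30,
                       T1_initial = 45, T1_delayed = 40)

SUBTYPE_LEVELS <- c("luminal_A", "luminal_B", "HER2_enriched", "triple_negative")

#' Synthetic cohort configuration
#'
#' Parameters of the virtual multiparametric-MRI cohort. Defaults mirror the
#' study population: 121 cases, five sequences with their acquisition voxel
#' spacings, tumor diameters 10-115 mm, and molecular-subtype frequencies
#' 57/49/4/11 out of 121 (luminal A/B, HER2-enriched, triple-negative).
#' `effect_size_d` is the standardized separation planted between the high
#' and low class of a TME component on the ideal discriminating texture
#' feature; its default 1.3 makes the ideal-feature AUC `pnorm(d/sqrt(2))
#' ~ 0.82`, the performance range the method is designed to operate in.
#'
#' @param n_cases Number of cases (>= 10; default 121).
#' @param seed Integer master seed.
#' @param sequences Named list of 5 voxel spacings (mm).
#' @param tumor_diameter_range_mm Length-2 positive increasing range.
#' @param effect_size_d Planted standardized class separation.
#' @param latent_correlation Correlation between the ECM and immune latents.
#' @param subtype_frequencies Named proportions summing to 1.
#' @param rim_width_mm Peritumoral rim-gradient width (default 6).
#' @param acquisition_noise_sd Additive white acquisition noise SD.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_cases = 121L,
                          seed = 1L,
                          sequences = SEQUENCE_SPACINGS,
                          tumor_diameter_range_mm = c(10, 115),
                          effect_size_d = 1.3,
                          latent_correlation = 0.3,
                          subtype_frequencies = c(luminal_A = 57 / 121,
                                                  luminal_B = 49 / 121,
                                                  HER2_enriched = 4 / 121,
                                                  triple_negative = 11 / 121),
                          rim_width_mm = 6,
                          acquisition_noise_sd = 2) {
  n_cases <- as.integer(n_cases)
  if (is.na(n_cases) || n_cases < 10L)
    stopf("n_cases must be at least 10 (downstream splits degenerate)")
  if (length(sequences) != 5L || is.null(names(sequences)))
    stopf("exactly 5 named sequences are required")
  if (length(tumor_diameter_range_mm) != 2L ||
      any(tumor_diameter_range_mm <= 0) ||
      diff(tumor_diameter_range_mm) < 0)
    stopf("tumor_diameter_range_mm must be positive and ordered")
  if (abs(sum(subtype_frequencies) - 1) > 1e-6)
    stopf("subtype frequencies must sum to 1")
  if (abs(latent_correlation) >= 1) stopf("latent_correlation must be in (-1, 1)")
  structure(list(n_cases = n_cases, seed = as.integer(seed),
                 sequences = sequences,
                 tumor_diameter_range_mm = tumor_diameter_range_mm,
                 effect_size_d = effect_size_d,
                 latent_correlation = latent_correlation,
                 subtype_frequencies = subtype_frequencies,
                 rim_width_mm = rim_width_mm,
                 acquisition_noise_sd = acquisition_noise_sd),
            class = "cohort_config")
}

#' Generate a synthetic multiparametric cohort
#'
#' Draws correlated ECM and immune latent scores, converts them into a TME
#' panel (collagen/laminin/nidogen immunoreactivity, regulatory and cytotoxic
#' T-cell counts, molecular subtype, median-split labels), and plants the
#' image-level signal: the intratumoral texture amplitude is a monotone
#' transform of `d * collagen_class + 0.25 * e_imm + noise` (total non-class
#' variance 1), where `e_imm` is the immune-specific latent component, so the
#' intratumoral intensity SD has binormal discriminability `d` against the
#' collagen label, rises with the Treg latent and falls with the CD8 latent.
#' The peritumoral rim amplitude mirrors this with the Treg class. Images are
#' materialized lazily per case by [generate_case()]; the cohort object
#' itself holds the panel and per-case geometry/seeds, so a fixed seed yields
#' a bit-identical cohort.
#'
#' @param config A [cohort_config()].
#' @param null_association If `TRUE`, texture/rim drivers are independent
#'   noise: no label-image association (negative control).
#' @return A `tme_cohort` with elements `config`, `panel` (data.frame) and
#'   `latent` (generator ground truth, incl. per-case amplitudes and seeds).
#' @export
generate_cohort <- function(config = cohort_config(), null_association = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_cases
  rho <- config$latent_correlation
  d <- config$effect_size_d
  with_seed(config$seed, {
    u_ecm <- rnorm(n)
    e_imm <- rnorm(n)
    u_imm <- rho * u_ecm + sqrt(1 - rho^2) * e_imm
    collagen <- exp(0.8 * u_ecm + 0.3 * rnorm(n))
    laminin <- exp(0.8 * u_ecm + 0.3 * rnorm(n))
    nidogen <- exp(0.8 * u_ecm + 0.3 * rnorm(n))
    treg_count <- round(exp(2.5 + 0.8 * u_imm + 0.3 * rnorm(n)))
    cd8_count <- round(exp(3.5 - 0.8 * u_imm + 0.3 * rnorm(n)))
    subtype <- factor(sample(SUBTYPE_LEVELS, n, replace = TRUE,
                             prob = config$subtype_frequencies),
                      levels = SUBTYPE_LEVELS)
    c_col <- as.integer(collagen > median(collagen))
    c_treg <- as.integer(treg_count > median(treg_count))
    if (null_association) {
      x_drv <- rnorm(n)
      y_drv <- rnorm(n)
    } else {
      x_drv <- d * c_col + 0.25 * e_imm + rnorm(n, sd = sqrt(1 - 0.25^2))
      y_drv <- d * c_treg + 0.25 * u_ecm + rnorm(n, sd = sqrt(1 - 0.25^2))
    }
    sigma_tex <- 10 * exp(0.25 * x_drv)
    rim_amp <- 12 * exp(0.25 * y_drv)
    diameter <- runif(n, config$tumor_diameter_range_mm[1],
                      config$tumor_diameter_range_mm[2])
    b_ratio <- runif(n, 0.65, 1)
    c_ratio <- runif(n, 0.65, 1)
  })
  case_seed <- vapply(seq_len(n), function(i)
    derive_seed(config$seed, paste0("case", i)), integer(1))
  panel <- data.frame(case_id = seq_len(n),
                      collagen = collagen, laminin = laminin,
                      nidogen = nidogen, treg_count = treg_count,
                      cd8_count = cd8_count, subtype = subtype)
  for (cmp in c("collagen", "laminin", "nidogen", "treg_count", "cd8_count"))
    panel[[paste0("label_", sub("_count$", "", cmp))]] <-
      dichotomize_by_median(panel[[cmp]])
  structure(list(config = config,
                 panel = panel,
                 null_association = null_association,
                 latent = data.frame(
                   case_id = seq_len(n), u_ecm = u_ecm, u_imm = u_imm,
                   e_imm = e_imm, x_driver = x_drv, y_driver = y_drv,
                   sigma_tex = sigma_tex, rim_amp = rim_amp,
                   diameter = diameter, b_ratio = b_ratio, c_ratio = c_ratio,
                   case_seed = case_seed)),
            class = "tme_cohort")
}

#' @rdname generate_cohort
#' @export
null_cohort <- function(config = cohort_config()) {
  generate_cohort(config, null_association = TRUE)
}

#' @export
print.tme_cohort <- function(x, ...) {
  cat(sprintf("<tme_cohort> %d cases, %d sequences%s\n", x$config$n_cases,
              length(x$config$sequences),
              if (isTRUE(x$null_association)) " (null: no label-image association)" else ""))
  print(table(x$panel$subtype))
  invisible(x)
}

#' Materialize the images and masks of one case
#'
#' Builds the per-sequence volumes of case `i` deterministically from the
#' cohort's stored geometry and per-case seeds: an ellipsoidal tumor with
#' random orientation, a shared continuous noise field sampled on every
#' sequence grid, intratumoral texture of amplitude `sigma_tex[i]`, a
#' peritumoral rim ramp of width `rim_width_mm` and amplitude `rim_amp[i]`,
#' and white acquisition noise.
#'
#' @param cohort A `tme_cohort`.
#' @param i Case index.
#' @param sequences Sequence tags to materialize (default: all five).
#' @return List with named lists `images` (`vol_image`) and `masks`
#'   (`vol_mask`).
#' @export
generate_case <- function(cohort, i, sequences = NULL) {
  stopifnot(inherits(cohort, "tme_cohort"))
  cfg <- cohort$config
  if (is.null(sequences)) sequences <- names(cfg$sequences)
  lat <- cohort$latent[i, ]
  a <- lat$diameter / 2
  b <- a * lat$b_ratio
  cc <- a * lat$c_ratio
  pad <- 14  # supports an 8 mm annulus plus the 6 mm rim
  E <- ceiling(a + pad)
  n1 <- 2L * E
  rot <- with_seed(as.integer(lat$case_seed), {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
  W <- with_seed(derive_seed(lat$case_seed, "field"),
                 array(rnorm(n1^3), dim = c(n1, n1, n1)))
  rg <- (a * b * cc)^(1 / 3)
  images <- list(); masks <- list()
  for (sq in sequences) {
    sp <- cfg$sequences[[sq]]
    nd <- pmax(2L, as.integer(ceiling(2 * E / sp)))
    ax <- lapply(1:3, function(k) (seq_len(nd[k]) - (nd[k] + 1) / 2) * sp[k])
    X <- rep(ax[[1]], times = nd[2] * nd[3])
    Y <- rep(rep(ax[[2]], each = nd[1]), times = nd[3])
    Z <- rep(ax[[3]], each = nd[1] * nd[2])
    lx <- rot[1, 1] * X + rot[2, 1] * Y + rot[3, 1] * Z
    ly <- rot[1, 2] * X + rot[2, 2] * Y + rot[3, 2] * Z
    lz <- rot[1, 3] * X + rot[2, 3] * Y + rot[3, 3] * Z
    rho <- sqrt((lx / a)^2 + (ly / b)^2 + (lz / cc)^2)
    inside <- rho <= 1
    aligned <- all(sp == 1) && all(nd == n1)
    field <- if (aligned) as.vector(W)
    else interp_trilinear(W, X + E + 0.5, Y + E + 0.5, Z + E + 0.5)
    dsurf <- (rho - 1) * rg
    ramp <- ifelse(!inside & dsurf <= cfg$rim_width_mm,
                   pmax(0, 1 - dsurf / cfg$rim_width_mm), 0)
    img <- 100 + inside * (SEQUENCE_CONTRAST[[sq]] + lat$sigma_tex * field) +
      ramp * lat$rim_amp * (1 + 0.3 * field)
    img <- img + with_seed(derive_seed(lat$case_seed, paste0("noise_", sq)),
                           rnorm(length(img), sd = cfg$acquisition_noise_sd))
    images[[sq]] <- vol_image(array(img, nd), sp)
    masks[[sq]] <- vol_mask(array(inside, nd), sp)
  }
  list(images = images, masks = masks)
}

#' Feature-space planted cohort
#'
#' Generates a feature table with one planted binormal discriminator of
#' standardized separation `d` (theoretical AUC `pnorm(d/sqrt(2))`) plus pure
#' noise features, and a balanced-probability binary label. This is the
#' feature-level counterpart of the image generator, used to calibrate the
#' selection and evaluation stages at scale.
#'
#' @param n Cases.
#' @param p_noise Number of pure-noise features.
#' @param d Planted separation (0 for a null table).
#' @param seed Integer seed.
#' @return List with matrix `X` (first column `planted`) and 0/1 vector `y`.
#' @export
planted_feature_table <- function(n, p_noise = 99L, d = 1.3, seed = 1L) {
  with_seed(seed, {
    y <- rbinom(n, 1L, 0.5)
    X <- cbind(planted = d * y + rnorm(n),
               matrix(rnorm(n * p_noise), n, p_noise,
                      dimnames = list(NULL, sprintf("noise_%03d", seq_len(p_noise)))))
    list(X = X, y = y)
  })
}

#' Write a cohort to disk
#'
#' Writes per-case NIfTI image/mask pairs for each sequence, the TME panel as
#' CSV, and a JSON manifest with the configuration and per-case seeds.
#'
#' @param cohort A `tme_cohort`.
#' @param dir Output directory (created if missing).
#' @param sequences Sequence tags to write (default: all).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, sequences = NULL) {
  stopifnot(inherits(cohort, "tme_cohort"))
  if (is.null(sequences)) sequences <- names(cohort$config$sequences)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(cohort$config$n_cases)) {
    case <- generate_case(cohort, i, sequences)
    for (sq in sequences) {
      write_volume(case$images[[sq]],
                   file.path(dir, sprintf("case%03d_%s_image.nii.gz", i, sq)))
      write_volume(case$masks[[sq]],
                   file.path(dir, sprintf("case%03d_%s_mask.nii.gz", i, sq)))
    }
  }
  utils::write.csv(cohort$panel, file.path(dir, "tme_panel.csv"),
                   row.names = FALSE)
  manifest <- list(config = cohort$config[setdiff(names(cohort$config), "sequences")],
                   sequences = cohort$config$sequences,
                   case_seeds = cohort$latent$case_seed,
                   null_association = cohort$null_association)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Endpoint labels from a TME panel
#'
#' Median-split binary labels for the five component endpoints and the two
#' composite endpoints: `ecm_overall` is the median split of the mean
#' z-scored ECM components (collagen, laminin, nidogen); `immune_overall`
#' averages z-scored Treg counts with sign-reversed z-scored CD8 counts.
#'
#' @param panel The `panel` data.frame of a cohort.
#' @param endpoint One of `collagen`, `laminin`, `nidogen`, `treg`, `cd8`,
#'   `ecm_overall`, `immune_overall`.
#' @return Integer 0/1 labels.
#' @export
panel_labels <- function(panel, endpoint) {
  z <- function(v) (v - mean(v)) / sd(v)
  switch(endpoint,
         collagen = panel$label_collagen,
         laminin = panel$label_laminin,
         nidogen = panel$label_nidogen,
         treg = panel$label_treg,
         cd8 = panel$label_cd8,
         ecm_overall = dichotomize_by_median(
           (z(panel$collagen) + z(panel$laminin) + z(panel$nidogen)) / 3),
         immune_overall = dichotomize_by_median(
           (z(panel$treg_count) - z(panel$cd8_count)) / 2),
         stopf("unknown endpoint '%s'", endpoint))
}
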