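#' Specification of a synthetic whole-body phantom
#'
#' Bundles the subject-level attributes that condition phantom generation:
#' sex, age, BMI, metabolic labels, per-depot fat fractions and the number of
#' transverse slices (whole-body protocols acquire 90--120 slices depending
#' on body height).
#'
#' @param sex 0 = male, 1 = female.
#' @param age years.
#' @param bmi kg/m^2; scales overall girth.
#' @param insulin_sensitivity Matsuda-like arbitrary units.
#' @param hba1c_pct glycated hemoglobin, percent.
#' @param fasting_glucose,glucose_2h mmol/l.
#' @param depot_fractions named vector in \[0,1\] over [adiponet_regions];
#'   the fraction of each region's voxels occupied by bright fat.
#' @param slice_count integer in \[90, 120\].
#' @param seed integer; all phantom randomness derives from it.
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(sex = 0, age = 45, bmi = 27,
                         insulin_sensitivity = 12, hba1c_pct = 5.4,
                         fasting_glucose = 5.0, glucose_2h = 6.0,
                         depot_fractions = default_depot_fractions(),
                         slice_count = 100L, seed = 1L) {
  slice_count <- as.integer(slice_count)
  if (is.na(slice_count) || slice_count < 90L || slice_count > 120L)
    stop("slice_count must be in [90, 120]")
  if (!all(adiponet_regions %in% names(depot_fractions)))
    stop("depot_fractions must name all regions: ",
         paste(adiponet_regions, collapse = ", "))
  depot_fractions <- depot_fractions[adiponet_regions]
  if (any(depot_fractions < 0 | depot_fractions > 1))
    stop("depot fractions must lie in [0, 1]")
  vals <- c(age = age, bmi = bmi, insulin_sensitivity = insulin_sensitivity,
            hba1c_pct = hba1c_pct, fasting_glucose = fasting_glucose,
            glucose_2h = glucose_2h)
  if (any(vals <= 0)) stop("physiological values must be positive")
  if (!sex %in% c(0, 1)) stop("sex must be 0 or 1")
  structure(list(sex = sex, age = age, bmi = bmi,
                 insulin_sensitivity = insulin_sensitivity,
                 hba1c_pct = hba1c_pct, fasting_glucose = fasting_glucose,
                 glucose_2h = glucose_2h, depot_fractions = depot_fractions,
                 slice_count = slice_count, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_depot_fractions <- function() {
  c(subcutaneous = 0.35, visceral_upper = 0.30, visceral_lower = 0.25,
    thigh = 0.30, arm = 0.25, neck = 0.20, breast = 0.20)
}

# Body plan: stacked elliptical cross-sections along the vertical axis.
# Vertical fractions of the grid: head [0, .09), neck [.09, .145),
# torso [.145, .38), abdomen [.38, .56), legs [.56, 1]; arms flank the trunk
# over [.15, .52).  Returns body mask + disjoint region masks.
phantom_geometry <- function(spec, nz, inplane) {
  n2 <- inplane[1]; n3 <- inplane[2]
  u <- seq(-1, 1, length.out = n2)            # anterior-posterior
  v <- seq(-1, 1, length.out = n3)            # left-right
  U <- matrix(u, n2, n3)
  V <- matrix(v, n2, n3, byrow = TRUE)
  g <- sqrt(spec$bmi / 25)
  female <- spec$sex == 1
  body <- array(FALSE, c(nz, n2, n3))
  reg <- lapply(adiponet_regions, function(r) array(FALSE, c(nz, n2, n3)))
  names(reg) <- adiponet_regions
  sh_ry <- if (female) 0.44 else 0.52
  for (z in seq_len(nz)) {
    t <- (z - 0.5) / nz
    slice_body <- matrix(FALSE, n2, n3)
    re_trunk <- NULL
    if (t < 0.09) {                                    # head
      slice_body <- (U / 0.30)^2 + (V / 0.20)^2 <= 1
    } else if (t < 0.145) {                            # neck
      slice_body <- (U / 0.20)^2 + (V / 0.16)^2 <= 1
      reg$neck[z, , ] <- slice_body
    } else if (t < 0.56) {                             # trunk
      if (t < 0.38) {
        frac <- (t - 0.145) / (0.38 - 0.145)
        ry <- (sh_ry + (0.38 - sh_ry) * frac) * g
      } else if (female) {
        ry <- (0.36 + 0.10 * (t - 0.38) / 0.18) * g
      } else {
        ry <- 0.40 * g
      }
      rx <- 0.50 * g
      bulge <- female && t >= 0.16 && t < 0.26
      rx_eff <- ifelse(U < 0 & bulge, rx * 1.18, rx)
      re_trunk <- sqrt((U / rx_eff)^2 + (V / ry)^2)
      trunk <- re_trunk <= 1
      slice_body <- trunk
      if (t >= 0.16 && t < 0.26)
        reg$breast[z, , ] <- trunk & re_trunk > 0.55 & U < 0
      if (t >= 0.38) {
        core <- sqrt((U / (0.50 * g))^2 + (V / (0.36 * g))^2)
        if (t < 0.47) reg$visceral_upper[z, , ] <- trunk & core <= 0.70
        else reg$visceral_lower[z, , ] <- trunk & core <= 0.70
      }
      reg$subcutaneous[z, , ] <- trunk & re_trunk > 0.78
      if (t >= 0.15 && t < 0.52) {                     # arms
        ra <- 0.10 * g
        ac <- ry + 0.13
        arm <- (U / (ra * 1.3))^2 + ((V - ac) / ra)^2 <= 1 |
               (U / (ra * 1.3))^2 + ((V + ac) / ra)^2 <= 1
        slice_body <- slice_body | arm
        reg$arm[z, , ] <- arm
      }
    } else {                                           # legs
      rl <- (0.16 - 0.09 * (t - 0.56) / 0.44) * g
      leg <- (U / (rl * 1.2))^2 + ((V - 0.18) / rl)^2 <= 1 |
             (U / (rl * 1.2))^2 + ((V + 0.18) / rl)^2 <= 1
      slice_body <- leg
      if (t < 0.75) reg$thigh[z, , ] <- leg
    }
    body[z, , ] <- slice_body
  }
  # enforce disjointness by priority; every region stays inside the body
  order_pri <- c("neck", "breast", "arm", "visceral_lower", "visceral_upper",
                 "thigh", "subcutaneous")
  taken <- array(FALSE, c(nz, n2, n3))
  for (r in order_pri) {
    reg[[r]] <- reg[[r]] & body & !taken
    taken <- taken | reg[[r]]
  }
  list(body = body, regions = reg[adiponet_regions])
}

#' Generate a synthetic whole-body phantom volume
#'
#' Builds a T1-like voxel volume from a [phantom_spec()]: stacked elliptical
#' cross-sections (head, torso, abdomen, pelvis, legs, arms), bright fat
#' (intensity ~1) against dim lean tissue (~0.5) and zero-air background.
#' Within each region mask the darkest-to-brightest fat placement follows a
#' seeded smooth random field, with the number of fat voxels equal to
#' `round(fraction * region size)` -- so fat extent and mean intensity are
#' monotone in the depot fraction, and identical seeds give bit-identical
#' volumes.  BMI scales girth; sex toggles the shoulder/hip ratio and breast
#' prominence.
#'
#' @param spec a [phantom_spec()].
#' @param profile a [grid_profile()]; sets in-plane dims and spacing.
#' @return A `body_volume`: list with `voxels` (slice x sagittal x coronal
#'   array), `body_mask`, `region_masks` (disjoint subsets of the body),
#'   `spacing`, `axis_order` and the originating `spec`.
#' @export
generate_phantom <- function(spec, profile = grid_profile("tiny")) {
  stopifnot(inherits(spec, "phantom_spec"))
  nz <- spec$slice_count
  inplane <- profile$inplane
  geo <- phantom_geometry(spec, nz, inplane)
  dims <- c(nz, inplane)
  vol <- with_rng_seed(spec$seed, {
    field <- blur_volume(array(runif(prod(dims)), dims),
                         sigma = max(0.8, 0.04 * min(inplane)))
    texture <- array(rnorm(prod(dims), sd = 0.03), dims)
    fat <- array(FALSE, dims)
    place_fat <- function(mask, frac) {
      vidx <- which(mask)
      nfat <- round(frac * length(vidx))
      if (nfat > 0) fat[vidx[order(field[vidx])][seq_len(nfat)]] <<- TRUE
    }
    for (r in adiponet_regions)
      place_fat(geo$regions[[r]], spec$depot_fractions[[r]])
    other <- geo$body & !Reduce(`|`, geo$regions)
    place_fat(other, 0.08)
    x <- array(0, dims)
    x[geo$body] <- pmax(0.5 + 0.5 * fat[geo$body] + texture[geo$body], 0.05)
    x
  })
  structure(list(voxels = vol, body_mask = geo$body,
                 region_masks = geo$regions, spacing = profile$spacing,
                 axis_order = c("vertical", "sagittal", "coronal"),
                 profile = profile$name, spec = spec),
            class = "body_volume")
}

#' @export
print.body_volume <- function(x, ...) {
  cat("<body_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, body fraction ",
      sprintf("%.1f%%", 100 * mean(x$body_mask)), "\n", sep = "")
  invisible(x)
}

#' Convert glycated hemoglobin between percent and mmol/mol
#'
#' Standard IFCC-NGSP linear relation `mmol/mol = 10.93 * pct - 23.5`
#' (the 48 mmol/mol diagnosis threshold corresponds to about 6.5%).
#' @param pct,mmolmol values to convert.
#' @export
hba1c_pct_to_mmolmol <- function(pct) 10.93 * pct - 23.5

#' @rdname hba1c_pct_to_mmolmol
#' @export
hba1c_mmolmol_to_pct <- function(mmolmol) (mmolmol + 23.5) / 10.93

#' Diagnosis labels from glycemic measurements
#'
#' Applies the diagnostic thresholds: diabetes (`Da`) if fasting glucose
#' strictly exceeds 7.0 mmol/l, or 2h post-challenge glucose >= 11.1 mmol/l,
#' or HbA1c >= 48 mmol/mol.  Prediabetes (`Db`) if not diabetic but impaired
#' fasting glucose (IFG) or impaired glucose tolerance (IGT) is present; the
#' extended label `Dg` adds subjects with concomitant IFG *and* IGT to the
#' diabetes cases.  IFG and IGT default to the ADA research bands
#' (fasting 5.6--6.9, 2h 7.8--11.0 mmol/l).
#'
#' @param fasting,g2h mmol/l; `hba1c_mmolmol` mmol/mol. Vectorized.
#' @param ifg_band,igt_band inclusive band limits, mmol/l.
#' @return data.frame with integer columns `Da`, `Db`, `Dg`.
#' @export
assign_diagnosis <- function(fasting, g2h, hba1c_mmolmol,
                             ifg_band = c(5.6, 6.9),
                             igt_band = c(7.8, 11.0)) {
  if (any(c(fasting, g2h, hba1c_mmolmol) < 0, na.rm = TRUE))
    stop("glycemic inputs must be nonnegative")
  da <- fasting > 7.0 | g2h >= 11.1 | hba1c_mmolmol >= 48
  ifg <- fasting >= ifg_band[1] & fasting <= ifg_band[2]
  igt <- g2h >= igt_band[1] & g2h <= igt_band[2]
  data.frame(Da = as.integer(da),
             Db = as.integer(!da & (ifg | igt)),
             Dg = as.integer(da | (ifg & igt)))
}

#' Microalbuminuria from the urinary albumin-to-creatinine ratio
#'
#' @param uacr mg/g creatinine; vectorized.
#' @return integer, 1 iff `uacr >= 30`.
#' @export
assign_microalbuminuria <- function(uacr) {
  if (any(uacr < 0, na.rm = TRUE)) stop("uACR must be nonnegative")
  as.integer(uacr >= 30)
}

#' Default generative label model
#'
#' Reads the label-model parameters recorded in the package configuration
#' (`inst/config/default.yaml`): latent-class prevalences, depot-fraction
#' levels per class, the insulin-sensitivity and glycemia response
#' coefficients and noise SDs, and the follow-up hazard model.
#' @param profile passed through to [default_config()].
#' @return Nested list of parameters.
#' @export
default_label_model <- function(profile = "tiny") {
  default_config(profile)$label_model
}

#' Generate a label-conditioned synthetic cohort
#'
#' Draws `n` subjects from a documented generative model and renders their
#' phantoms.  Causal ordering: a latent metabolic class (normoglycemic /
#' prediabetic / diabetic, configured prevalences) sets the lower visceral
#' fat fraction; insulin sensitivity decreases with the lower-visceral and
#' thigh depot load; fasting/2h glucose and HbA1c rise as insulin sensitivity
#' falls (plus noise); diagnosis labels then follow from the glycemic
#' thresholds, so the diabetes signal is anatomically localized in the lower
#' visceral depot.  Follow-up event times are exponential with
#' glycemia-dependent hazards and administrative censoring.
#'
#' With `config$signal_mode = "pattern"`, the lower and upper visceral
#' fractions are complementary (`f_upper = budget - f_lower`), so diseased
#' and healthy subjects carry matched total and visceral fat and differ only
#' in *where* within the visceral compartment the fat sits.
#'
#' @param n cohort size (>= 1).
#' @param config label-model parameters, see [default_label_model()].
#' @param seed integer master seed.
#' @param profile a [grid_profile()].
#' @param volumes if `FALSE`, skip phantom rendering (labels only).
#' @return list with `volumes`, `labels` (one row per subject), `followup`,
#'   plus the config/seed/profile used.
#' @export
generate_cohort <- function(n, config = default_label_model(), seed = 1L,
                            profile = grid_profile("tiny"), volumes = TRUE) {
  if (n < 1) stop("n must be >= 1")
  lm <- config
  out <- with_rng_seed(seed, {
    pd <- lm$prevalence$diabetes
    pp <- lm$prevalence$prediabetes
    cls <- sample(c("normo", "pre", "diabetes"), n, replace = TRUE,
                  prob = c(1 - pd - pp, pp, pd))
    sex <- rbinom(n, 1, 0.5)
    age <- pmin(pmax(rnorm(n, 45, 12), 20), 80)
    bmi <- pmin(pmax(rnorm(n, 27, 4.5), 18), 45)
    dp <- lm$depots
    clamp01 <- function(x) pmin(pmax(x, 0.02), 0.95)
    f_vl <- clamp01(unlist(dp$visceral_lower_by_class)[cls] +
                      rnorm(n, 0, dp$sd))
    base <- unlist(dp$base)
    frac <- sapply(adiponet_regions, function(r)
      clamp01(base[[r]] + rnorm(n, 0, dp$sd)))
    frac <- matrix(frac, nrow = n,
                   dimnames = list(NULL, adiponet_regions))
    frac[, "visceral_lower"] <- f_vl
    if (identical(lm$signal_mode, "pattern")) {
      frac[, "visceral_upper"] <- clamp01(lm$pattern$budget - f_vl)
    }
    frac[, "subcutaneous"] <-
      clamp01(frac[, "subcutaneous"] + dp$bmi_subq_slope * (bmi - 25))
    frac[sex == 1, "breast"] <-
      clamp01(dp$female_breast + rnorm(sum(sex == 1), 0, dp$sd))
    ins <- lm$insulin
    is_val <- pmax(ins$base - ins$visc_coef * frac[, "visceral_lower"] -
                     ins$thigh_coef * frac[, "thigh"] +
                     rnorm(n, 0, ins$sd), 0.5)
    deficit <- pmax(ins$deficit_ref - is_val, 0)
    gl <- lm$glycemia
    fasting <- pmax(gl$fasting$base + gl$fasting$coef * deficit +
                      rnorm(n, 0, gl$fasting$sd), 2.5)
    g2h <- pmax(gl$g2h$base + gl$g2h$coef * deficit +
                  rnorm(n, 0, gl$g2h$sd), 2.5)
    hba1c <- pmax(gl$hba1c$base + gl$hba1c$coef * deficit +
                    rnorm(n, 0, gl$hba1c$sd), 3.5)
    dg <- assign_diagnosis(fasting, g2h, hba1c_pct_to_mmolmol(hba1c))
    fu <- lm$followup
    uacr <- rlnorm(n, log(fu$uacr_meanlog_ref), fu$uacr_sdlog)
    haz_d <- fu$diabetes_h0 * exp(fu$diabetes_beta * (hba1c - gl$hba1c$base))
    haz_m <- fu$microalb_h0 * exp(fu$microalb_beta * (hba1c - gl$hba1c$base) +
                                    fu$microalb_uacr_beta *
                                      log(uacr / fu$uacr_meanlog_ref))
    td <- rexp(n, haz_d); cd <- pmin(fu$horizon, rexp(n, 1 / fu$censor_mean))
    tm <- rexp(n, haz_m); cm <- pmin(fu$horizon, rexp(n, 1 / fu$censor_mean))
    slice_count <- sample(90:120, n, replace = TRUE)
    phantom_seed <- sample.int(.Machine$integer.max - 1L, n)
    labels <- data.frame(
      id = seq_len(n), sex = sex, age = age, bmi = bmi,
      insulin_sensitivity = is_val, hba1c = hba1c,
      hba1c_mmolmol = hba1c_pct_to_mmolmol(hba1c),
      fasting_glucose = fasting, glucose_2h = g2h,
      Da = dg$Da, Db = dg$Db, Dg = dg$Dg, latent_class = cls,
      slice_count = slice_count, phantom_seed = phantom_seed)
    labels <- cbind(labels,
                    setNames(as.data.frame(frac),
                             paste0("depot_", adiponet_regions)))
    followup <- data.frame(
      id = seq_len(n),
      time_to_diabetes = pmin(td, cd), diabetes_event = as.integer(td <= cd),
      time_to_microalbuminuria = pmin(tm, cm),
      microalbuminuria_event = as.integer(tm <= cm),
      baseline_uacr = uacr,
      microalbuminuria_baseline = assign_microalbuminuria(uacr))
    list(labels = labels, followup = followup)
  })
  vols <- NULL
  if (volumes) {
    vols <- lapply(seq_len(n), function(i) {
      row <- out$labels[i, ]
      sp <- phantom_spec(
        sex = row$sex, age = row$age, bmi = row$bmi,
        insulin_sensitivity = row$insulin_sensitivity,
        hba1c_pct = row$hba1c, fasting_glucose = row$fasting_glucose,
        glucose_2h = row$glucose_2h,
        depot_fractions = setNames(
          as.numeric(row[paste0("depot_", adiponet_regions)]),
          adiponet_regions),
        slice_count = row$slice_count, seed = row$phantom_seed)
      generate_phantom(sp, profile)
    })
  }
  list(volumes = vols, labels = out$labels, followup = out$followup,
       config = config, seed = seed, profile = profile)
}

#' Draw synthetic scan embeddings from the default subtype mixture
#'
#' Emulates the 128-dimensional embedding vectors that the network's
#' penultimate layer produces, as a well-separated spherical Gaussian
#' mixture: `k` subtype centres drawn i.i.d. N(0, `center_sd`^2) per
#' coordinate, members scattered N(centre, `within_sd`^2).  The defaults
#' (4 subtypes, centre SD 1.5, within-cluster SD 0.5) give clearly separated
#' groups in 128 dimensions.
#'
#' @param n number of embeddings.
#' @param k number of subtypes.
#' @param dim embedding dimension.
#' @param center_sd,within_sd mixture scale parameters.
#' @param seed integer.
#' @return list with `embeddings` (n x dim matrix) and `subtype`.
#' @export
simulate_embeddings <- function(n = 400, k = 4, dim = 128,
                                center_sd = 1.5, within_sd = 0.5, seed = 1L) {
  with_rng_seed(seed, {
    centers <- matrix(rnorm(k * dim, sd = center_sd), k, dim)
    subtype <- sample(rep_len(seq_len(k), n))
    emb <- centers[subtype, , drop = FALSE] +
      matrix(rnorm(n * dim, sd = within_sd), n, dim)
    list(embeddings = emb, subtype = subtype)
  })
}
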