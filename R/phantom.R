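#' Anatomical model of a digital hip phantom
#'
#' Describes two femoral heads (cancellous core wrapped in a cortical shell)
#' and two acetabular domes as analytic spheres on a voxel grid. The default
#' grid is 96^3 at isotropic 2.95 mm — desk-scale, while keeping true mm
#' geometry so ROI diameters stated in cm are meaningful.
#'
#' @param volume_shape Integer length-3, voxels per axis.
#' @param voxel_spacing mm per voxel per axis (scalar for isotropic).
#' @param femoral_head_radius Head sphere radius in mm.
#' @param cortical_shell_thickness Thickness of the cortical shell in mm;
#'   must be smaller than the head radius.
#' @param acetabular_dome_radius Dome sphere radius in mm.
#' @param femoral_head_center_left,femoral_head_center_right Head centers in
#'   mm world coordinates; defaults place both heads symmetrically inside
#'   the default grid.
#' @param acetabular_dome_center_left,acetabular_dome_center_right Dome
#'   centers in mm; defaults sit superomedial to each head without touching
#'   it.
#' @return An object of class `anatomy_model`.
#' @export
#' @examples
#' anatomy_model()
anatomy_model <- function(volume_shape = c(96L, 96L, 96L),
                          voxel_spacing = 2.95,
                          femoral_head_radius = 22,
                          cortical_shell_thickness = 3,
                          acetabular_dome_radius = 10,
                          femoral_head_center_left = c(85, 140, 110),
                          femoral_head_center_right = c(195, 140, 110),
                          acetabular_dome_center_left = c(105, 140, 138),
                          acetabular_dome_center_right = c(175, 140, 138)) {
  voxel_spacing <- expand_spacing(voxel_spacing)
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 2L))
    stop("`volume_shape` must be 3 integers >= 2", call. = FALSE)
  if (femoral_head_radius <= 0 || acetabular_dome_radius <= 0 ||
      cortical_shell_thickness <= 0)
    stop("all radii and the shell thickness must be positive", call. = FALSE)
  if (cortical_shell_thickness >= femoral_head_radius)
    stop("cortical shell thickness must be smaller than the head radius",
         call. = FALSE)
  a <- structure(
    list(
      volume_shape = volume_shape,
      voxel_spacing = voxel_spacing,
      femoral_head_radius = femoral_head_radius,
      cortical_shell_thickness = cortical_shell_thickness,
      acetabular_dome_radius = acetabular_dome_radius,
      femoral_head_center_left = as.numeric(femoral_head_center_left),
      femoral_head_center_right = as.numeric(femoral_head_center_right),
      acetabular_dome_center_left = as.numeric(acetabular_dome_center_left),
      acetabular_dome_center_right = as.numeric(acetabular_dome_center_right)
    ),
    class = "anatomy_model"
  )
  ext <- volume_extent(a$volume_shape, a$voxel_spacing)
  for (side in c("left", "right")) {
    ctr <- a[[paste0("femoral_head_center_", side)]]
    if (any(ctr - femoral_head_radius < 0) ||
        any(ctr + femoral_head_radius > ext))
      stop(sprintf("%s femoral head sphere extends outside the volume", side),
           call. = FALSE)
  }
  a
}

#' Expected tracer uptake rates per tissue class
#'
#' Expected photon counts per voxel for each tissue class of the phantom.
#' Defaults follow the cohort-level mean uptakes of the study population:
#' 66.3 counts in an avascular (affected) cancellous head, 201.3 in a viable
#' one, and 319.1 at the acetabular dome; the cortical shell is set hotter
#' than cancellous bone, as bone-seeking tracers accumulate in cortex, and
#' the soft-tissue background is low.
#'
#' @param background_rate Expected counts/voxel outside bone.
#' @param cancellous_head_rate_affected Rate in the affected head's
#'   cancellous core.
#' @param cancellous_head_rate_unaffected Rate in the contralateral head.
#' @param cortical_rate Rate in the cortical shells.
#' @param acetabular_rate Rate in the acetabular domes.
#' @param noise_model `"poisson"` for Poisson-sampled counts, `"none"` for a
#'   noiseless phantom whose voxels equal the rates exactly.
#' @param seed Integer RNG seed; mandatory when `noise_model = "poisson"`.
#' @return An object of class `uptake_params`.
#' @export
uptake_params <- function(background_rate = 20,
                          cancellous_head_rate_affected = 66.3,
                          cancellous_head_rate_unaffected = 201.3,
                          cortical_rate = 400,
                          acetabular_rate = 319.1,
                          noise_model = c("poisson", "none"),
                          seed = NULL) {
  noise_model <- match.arg(noise_model)
  rates <- c(background_rate, cancellous_head_rate_affected,
             cancellous_head_rate_unaffected, cortical_rate, acetabular_rate)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all uptake rates must be finite and >= 0", call. = FALSE)
  if (noise_model == "poisson" && is.null(seed))
    stop("`seed` is required when noise_model = \"poisson\"", call. = FALSE)
  structure(
    list(
      background_rate = background_rate,
      cancellous_head_rate_affected = cancellous_head_rate_affected,
      cancellous_head_rate_unaffected = cancellous_head_rate_unaffected,
      cortical_rate = cortical_rate,
      acetabular_rate = acetabular_rate,
      noise_model = noise_model,
      seed = seed
    ),
    class = "uptake_params"
  )
}

# Squared distance from every voxel center to `center` (mm), as a 3-D array.
voxel_dist2 <- function(shape, spacing, center) {
  dx2 <- (axis_centers(shape[1], spacing[1]) - center[1])^2
  dy2 <- (axis_centers(shape[2], spacing[2]) - center[2])^2
  dz2 <- (axis_centers(shape[3], spacing[3]) - center[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+")
}

#' Build a digital hip phantom
#'
#' Renders the anatomy model onto the voxel grid (a voxel belongs to a shape
#' when its center lies inside the analytic sphere; no partial-volume
#' blending) and fills each tissue class with its expected uptake rate,
#' Poisson-sampling each voxel when `noise_model = "poisson"`. Femoral heads
#' take precedence over acetabular domes should the spheres ever overlap.
#'
#' @param anatomy An [anatomy_model()].
#' @param uptake An [uptake_params()].
#' @param affected_side `"left"` or `"right"`: which head receives the
#'   affected cancellous rate.
#' @return A list with elements `counts` (a `voxel_volume`) and `labels`
#'   (a `structure_volume`).
#' @export
#' @examples
#' ph <- build_hip_phantom(anatomy_model(), uptake_params(noise_model = "none"))
#' ph$labels
build_hip_phantom <- function(anatomy, uptake,
                              affected_side = c("right", "left")) {
  stopifnot(inherits(anatomy, "anatomy_model"), inherits(uptake, "uptake_params"))
  affected_side <- match.arg(affected_side)
  shape <- anatomy$volume_shape
  spacing <- anatomy$voxel_spacing
  r_head2 <- anatomy$femoral_head_radius^2
  r_core2 <- (anatomy$femoral_head_radius - anatomy$cortical_shell_thickness)^2
  r_dome2 <- anatomy$acetabular_dome_radius^2

  d2_head <- list(
    left = voxel_dist2(shape, spacing, anatomy$femoral_head_center_left),
    right = voxel_dist2(shape, spacing, anatomy$femoral_head_center_right)
  )
  dome_mask <-
    voxel_dist2(shape, spacing, anatomy$acetabular_dome_center_left) <= r_dome2 |
    voxel_dist2(shape, spacing, anatomy$acetabular_dome_center_right) <= r_dome2

  codes <- tissue_codes()
  labels <- array(codes[["background"]], dim = shape)
  rates <- array(uptake$background_rate, dim = shape)
  labels[dome_mask] <- codes[["acetabular_dome"]]
  rates[dome_mask] <- uptake$acetabular_rate
  for (side in c("left", "right")) {
    head <- d2_head[[side]] <= r_head2
    core <- d2_head[[side]] <= r_core2
    shell <- head & !core
    labels[shell] <- codes[["cortical"]]
    rates[shell] <- uptake$cortical_rate
    labels[core] <- codes[["cancellous"]]
    rates[core] <- if (side == affected_side)
      uptake$cancellous_head_rate_affected
    else uptake$cancellous_head_rate_unaffected
  }

  counts <- if (uptake$noise_model == "poisson") {
    set.seed(uptake$seed)
    array(stats::rpois(length(rates), lambda = rates), dim = shape)
  } else rates

  list(counts = voxel_volume(counts, spacing),
       labels = structure_volume(array(as.integer(labels), dim = shape), spacing))
}

#' Specification of a synthetic patient cohort
#'
#' Parameterizes the two outcome groups' uptake-ratio distributions as
#' truncated normals. Each distribution is given as
#' `c(mean, sd, lower, upper)`: `mean` is the mean of the *truncated*
#' distribution (the quantity reported for a patient group), `sd` the
#' pre-truncation (parent) standard deviation, back-computed from a group's
#' 95% CI half-width as `half_width * sqrt(n) / 1.96`.
#'
#' Defaults reproduce the study cohort: 6 patients who develop femoral-head
#' osteonecrosis (ONFH) and 24 who achieve union; head-to-head ratio groups
#' at mean 0.33 (bounds 0.18–0.45) and 1.30 (bounds 0.55–2.50), so that the
#' groups sit on opposite sides of the 0.5 cutoff as in the observed sample;
#' head-to-acetabulum ratio groups at 0.22 and 0.93, with the ONFH bounds
#' allowed to cross the 0.3 cutoff (the observed operating point there was
#' not perfectly sensitive). A fifth of the cohort is flagged
#' contralateral-incomparable (implant, contralateral ONFH, or
#' osteoarthritis, in the observed 4:1:1 mix).
#'
#' @param n_onfh,n_union Group sizes.
#' @param ratio_distribution_onfh,ratio_distribution_union Head-to-head
#'   ratio distributions, `c(mean, sd, lower, upper)`.
#' @param acet_distribution_onfh,acet_distribution_union Head-to-acetabulum
#'   ratio distributions, same form.
#' @param fraction_incomparable_contralateral Fraction of patients whose
#'   contralateral hip cannot serve as reference.
#' @param seed Integer RNG seed (mandatory).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_onfh = 6L,
                        n_union = 24L,
                        ratio_distribution_onfh =
                          c(mean = 0.33, sd = 0.05 * sqrt(6) / 1.96,
                            lower = 0.18, upper = 0.45),
                        ratio_distribution_union =
                          c(mean = 1.30, sd = 0.27 * sqrt(24) / 1.96,
                            lower = 0.55, upper = 2.50),
                        acet_distribution_onfh =
                          c(mean = 0.22, sd = 0.04 * sqrt(6) / 1.96,
                            lower = 0.10, upper = 0.40),
                        acet_distribution_union =
                          c(mean = 0.93, sd = 0.21 * sqrt(24) / 1.96,
                            lower = 0.35, upper = 2.20),
                        fraction_incomparable_contralateral = 0.2,
                        seed) {
  if (missing(seed) || is.null(seed))
    stop("`seed` is mandatory for cohort simulation", call. = FALSE)
  n_onfh <- as.integer(n_onfh); n_union <- as.integer(n_union)
  if (n_onfh < 0L || n_union < 0L)
    stop("group sizes must be nonnegative", call. = FALSE)
  if (n_onfh + n_union == 0L)
    stop("cohort is empty: both group sizes are zero", call. = FALSE)
  f <- fraction_incomparable_contralateral
  if (!is.finite(f) || f < 0 || f > 1)
    stop("`fraction_incomparable_contralateral` must be in [0, 1]",
         call. = FALSE)
  dists <- list(ratio_distribution_onfh = ratio_distribution_onfh,
                ratio_distribution_union = ratio_distribution_union,
                acet_distribution_onfh = acet_distribution_onfh,
                acet_distribution_union = acet_distribution_union)
  for (nm in names(dists)) {
    d <- dists[[nm]]
    if (length(d) != 4L || any(!is.finite(d)))
      stop(sprintf("`%s` must be c(mean, sd, lower, upper)", nm), call. = FALSE)
    if (d[[2]] < 0) stop(sprintf("`%s`: sd must be >= 0", nm), call. = FALSE)
    if (d[[3]] >= d[[4]])
      stop(sprintf("`%s`: truncation bounds must satisfy lower < upper", nm),
           call. = FALSE)
    if (d[[1]] < d[[3]] || d[[1]] > d[[4]])
      stop(sprintf("`%s`: mean must lie within the truncation bounds", nm),
           call. = FALSE)
    names(dists[[nm]]) <- c("mean", "sd", "lower", "upper")
  }
  structure(
    c(list(n_onfh = n_onfh, n_union = n_union), dists,
      list(fraction_incomparable_contralateral = f,
           seed = as.integer(seed))),
    class = "cohort_spec"
  )
}

# One group's worth of ratio draws: truncated normal whose truncated mean
# equals the stated group mean (parent location solved numerically).
draw_group_ratios <- function(n, dist) {
  if (n == 0L) return(numeric(0))
  if (dist[["sd"]] == 0) return(rep(dist[["mean"]], n))
  mu0 <- tnorm_calibrate_location(dist[["mean"]], dist[["sd"]],
                                  dist[["lower"]], dist[["upper"]])
  rtnorm(n, mu0, dist[["sd"]], dist[["lower"]], dist[["upper"]])
}

#' Simulate a patient cohort
#'
#' Draws a cohort of patient records with known outcome labels and true
#' uptake ratios from the group distributions of a [cohort_spec()]. The
#' result is a pure function of the spec (including its seed): identical
#' specs give identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame of patient records with columns `patient_id`,
#'   `affected_side`, `contralateral_status` (`healthy`/`implant`/`onfh`/`oa`),
#'   `outcome` (`onfh`/`union`), `head_to_head_ratio`,
#'   `head_to_acetabulum_ratio`, landmark coordinate columns (filled by the
#'   phantom pipeline, `NA` here) and volume file path columns.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(seed = 1))
#' table(cohort$outcome)
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_onfh + spec$n_union
  outcome <- c(rep("onfh", spec$n_onfh), rep("union", spec$n_union))
  hh <- c(draw_group_ratios(spec$n_onfh, spec$ratio_distribution_onfh),
          draw_group_ratios(spec$n_union, spec$ratio_distribution_union))
  ha <- c(draw_group_ratios(spec$n_onfh, spec$acet_distribution_onfh),
          draw_group_ratios(spec$n_union, spec$acet_distribution_union))
  affected_side <- sample(c("left", "right"), n, replace = TRUE)
  status <- rep("healthy", n)
  n_inc <- round(spec$fraction_incomparable_contralateral * n)
  if (n_inc > 0) {
    idx <- sample.int(n, n_inc)
    status[idx] <- sample(c("implant", "onfh", "oa"), n_inc, replace = TRUE,
                          prob = c(4, 1, 1) / 6)
  }
  rec <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    affected_side = affected_side,
    contralateral_status = status,
    outcome = outcome,
    head_to_head_ratio = hh,
    head_to_acetabulum_ratio = ha,
    head_affected_x = NA_real_, head_affected_y = NA_real_,
    head_affected_z = NA_real_,
    head_unaffected_x = NA_real_, head_unaffected_y = NA_real_,
    head_unaffected_z = NA_real_,
    acetabulum_affected_x = NA_real_, acetabulum_affected_y = NA_real_,
    acetabulum_affected_z = NA_real_,
    counts_path = NA_character_, labels_path = NA_character_,
    stringsAsFactors = FALSE
  )
  class(rec) <- c("patient_cohort", "data.frame")
  rec
}

manifest_required_cols <- function() {
  c("patient_id", "affected_side", "contralateral_status", "outcome",
    "head_to_head_ratio", "head_to_acetabulum_ratio")
}

#' Write / read a cohort manifest CSV
#'
#' The manifest is a plain CSV, one row per patient, carrying the outcome
#' label, the contralateral-hip status, the (optional) true ratios and the
#' mm landmark coordinates plus volume file paths for phantom-backed
#' cohorts. `read_cohort_manifest(write_cohort_manifest(x))` is the
#' identity, field for field.
#'
#' @param records A patient cohort data frame ([simulate_cohort()]).
#' @param path CSV file path.
#' @return `write_cohort_manifest` returns `path` invisibly;
#'   `read_cohort_manifest` returns the cohort data frame.
#' @export
write_cohort_manifest <- function(records, path) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(manifest_required_cols(), names(records))
  if (length(missing_cols))
    stop("records lack required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- records
  for (col in names(out)) {                # full precision: exact round-trip
    if (is.double(out[[col]])) {
      txt <- sprintf("%.17g", out[[col]])
      txt[is.na(out[[col]])] <- NA_character_
      out[[col]] <- txt
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort_manifest
#' @export
read_cohort_manifest <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  missing_cols <- setdiff(manifest_required_cols(), names(rec))
  if (length(missing_cols))
    stop("manifest is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(rec)) {
    bad_side <- which(!rec$affected_side %in% c("left", "right"))
    if (length(bad_side))
      stop(sprintf("manifest row %d: invalid affected_side %s",
                   bad_side[1], shQuote(rec$affected_side[bad_side[1]])),
           call. = FALSE)
    bad_status <- which(!rec$contralateral_status %in%
                          c("healthy", "implant", "onfh", "oa"))
    if (length(bad_status))
      stop(sprintf("manifest row %d: invalid contralateral_status %s",
                   bad_status[1],
                   shQuote(rec$contralateral_status[bad_status[1]])),
           call. = FALSE)
    bad_out <- which(!rec$outcome %in% c("onfh", "union"))
    if (length(bad_out))
      stop(sprintf("manifest row %d: invalid outcome %s",
                   bad_out[1], shQuote(rec$outcome[bad_out[1]])),
           call. = FALSE)
  }
  numeric_cols <- c(
    "head_to_head_ratio", "head_to_acetabulum_ratio",
    grep("^(head_(un)?affected|acetabulum_affected)_[xyz]$", names(rec),
         value = TRUE)
  )
  for (col in intersect(numeric_cols, names(rec)))
    rec[[col]] <- as.numeric(rec[[col]])
  for (col in c("counts_path", "labels_path"))
    if (col %in% names(rec)) rec[[col]] <- as.character(rec[[col]])
  class(rec) <- c("patient_cohort", "data.frame")
  rec
}
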