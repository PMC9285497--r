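## Scenario factory: region-tagged axisymmetric geometries for the three
## anatomical configurations of an osteoid osteoma plus an ex-vivo style
## validation layout. Coordinates are cylindrical (r, z) in the half-plane
## r >= 0; millimetres at this interface, metres inside the mesh; origin at
## the centre of the electrode active tip, z parallel to the electrode.

.default_geometry_params <- function() {
  list(
    electrode_radius    = 0.7365, # mm (17 gauge outer diameter 1.473 mm)
    tip_length          = 7.5,    # mm active tip
    nidus_radius        = 5,      # mm (1 cm sphere)
    sclerosis_thickness = 1,      # mm (scenario a)
    trabecular_gap      = 1,      # mm gap between nidus rim and cortical wall
    cortical_thickness  = 4,      # mm radial wall thickness (a, b)
    cortical_half_z     = 10,     # mm half-thickness of the cortical slab (c)
    cortical_r_extent   = 36,     # mm radial extent of the cortical slab (c)
    lamella_thickness   = 3,      # mm cortical lamella (validation)
    domain_size         = 40     # mm: r_max = z_max = -z_min
  )
}

## F(z) = int sqrt(R^2 - z^2) dz  (antiderivative, |z| <= R)
.circ_F <- function(z, R) (z * sqrt(pmax(R^2 - z^2, 0)) + R^2 * asin(pmin(pmax(z / R, -1), 1))) / 2

## Area of {0 <= r <= a, r^2 + z^2 <= R^2, z >= zlow} (planar, half-plane).
.area_strip_disc <- function(R, a, zlow) {
  zl <- max(zlow, -R)
  if (zl >= R) return(0)
  if (a >= R) return(.circ_F(R, R) - .circ_F(zl, R))
  z0 <- sqrt(R^2 - a^2)
  area <- 0
  if (zl < -z0) {
    area <- area + .circ_F(-z0, R) - .circ_F(zl, R)
  }
  area <- area + a * (z0 - max(zl, -z0))
  area + .circ_F(R, R) - .circ_F(z0, R)
}

#' Build a region-tagged axisymmetric scenario geometry
#'
#' Constructs one of the model's anatomical configurations in the (r, z)
#' half-plane (millimetres, origin at the centre of the electrode active
#' tip):
#' * `"a"` — nidus surrounded by a sclerotic layer, then trabecular bone,
#'   a radial cortical wall, and muscle;
#' * `"b"` — nidus directly in trabecular bone (no sclerosis) near the
#'   cortical wall;
#' * `"c"` — intracortical nidus: a cortical slab surrounds the tumour, with
#'   muscle beyond it (closest in the direction parallel to the electrode);
#' * `"validation"` — ex-vivo style layout: the nidus sits behind a
#'   parameterisable cortical lamella separating it from soft tissue, with
#'   three temperature probes at 0, 5 and 10 mm from the periosteum plane.
#'
#' Every geometry includes the metallic electrode (active tip straddling the
#' origin) and its plastic-insulated shaft extending out of the domain top.
#' The nidus is a half-disc of radius 5 mm (1 cm sphere) centred on the
#' symmetry axis by default.
#'
#' @param scenario_id One of `"a"`, `"b"`, `"c"`, `"validation"`.
#' @param overrides Named list overriding declared parameters (mm):
#'   `nidus_radius`, `sclerosis_thickness`, `trabecular_gap`,
#'   `cortical_thickness`, `cortical_half_z`, `cortical_r_extent`,
#'   `lamella_thickness`, `domain_size`, `electrode_radius`, `tip_length`.
#' @return An object of class `region_geometry`: parameters, a vectorised
#'   point classifier, per-region analytic planar areas (mm^2), the circular
#'   and straight interface locations used by the mesher, probe points
#'   (validation only) and the bounding box.
#' @examples
#' g <- build_scenario("a")
#' g$regions
#' @export
build_scenario <- function(scenario_id, overrides = list()) {
  if (!is.character(scenario_id) || length(scenario_id) != 1L ||
      !scenario_id %in% c("a", "b", "c", "validation"))
    stop("unknown scenario_id: must be one of 'a', 'b', 'c', 'validation'")
  p <- .default_geometry_params()
  for (nm in names(overrides)) {
    if (!nm %in% names(p)) stop("unknown geometry parameter: '", nm, "'")
    v <- overrides[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("geometry parameter '", nm, "' must be a positive number")
    p[[nm]] <- v
  }

  re <- p$electrode_radius; th <- p$tip_length / 2
  Rn <- p$nidus_radius;     D  <- p$domain_size
  if (re >= Rn) stop("electrode_radius must be smaller than nidus_radius")
  if (th >= D)  stop("tip_length larger than the domain")

  ## scenario-specific derived dimensions (mm)
  Rs <- Rn + p$sclerosis_thickness                 # sclerosis outer radius (a)
  Rci <- switch(scenario_id,
    a = Rs + p$trabecular_gap,
    b = Rn + p$trabecular_gap,
    NA_real_)
  Rco <- if (!is.na(Rci)) Rci + p$cortical_thickness else NA_real_
  chz <- p$cortical_half_z; crx <- p$cortical_r_extent
  zb  <- -(Rn + p$lamella_thickness)               # periosteum plane (valid.)

  if (scenario_id %in% c("a", "b") && Rco >= D)
    stop("cortical_thickness/domain_size: cortical wall reaches the outer boundary")
  if (scenario_id == "c") {
    if (chz <= Rn) stop("cortical_half_z must exceed nidus_radius")
    if (crx <= Rn || crx >= D) stop("cortical_r_extent must lie between nidus_radius and domain_size")
  }
  if (scenario_id == "validation" && -zb >= D)
    stop("lamella_thickness: periosteum plane falls outside the domain")
  if (scenario_id == "a" && Rs >= D) stop("sclerosis_thickness too large for the domain")

  classify <- switch(scenario_id,
    a = function(r, z) {
      d <- sqrt(r^2 + z^2)
      ifelse(r <= re & z >= -th & z <= th, "electrode",
      ifelse(r <= re & z > th, "plastic",
      ifelse(d <= Rn, "nidus",
      ifelse(d <= Rs, "sclerotic",
      ifelse(r <= Rci, "trabecular",
      ifelse(r <= Rco, "cortical", "muscle"))))))
    },
    b = function(r, z) {
      d <- sqrt(r^2 + z^2)
      ifelse(r <= re & z >= -th & z <= th, "electrode",
      ifelse(r <= re & z > th, "plastic",
      ifelse(d <= Rn, "nidus",
      ifelse(r <= Rci, "trabecular",
      ifelse(r <= Rco, "cortical", "muscle")))))
    },
    c = function(r, z) {
      d <- sqrt(r^2 + z^2)
      ifelse(r <= re & z >= -th & z <= th, "electrode",
      ifelse(r <= re & z > th, "plastic",
      ifelse(d <= Rn, "nidus",
      ifelse(abs(z) <= chz & r <= crx, "cortical", "muscle"))))
    },
    validation = function(r, z) {
      d <- sqrt(r^2 + z^2)
      ifelse(r <= re & z >= -th & z <= th, "electrode",
      ifelse(r <= re & z > th, "plastic",
      ifelse(d <= Rn, "nidus",
      ifelse(z >= zb, "cortical", "muscle"))))
    })

  ## analytic planar region areas (mm^2); strip = electrode + plastic column
  H <- 2 * D
  a_elec <- re * p$tip_length
  a_plas <- re * (D - th)
  strip_total <- a_elec + a_plas                      # {r<=re, z>=-th}
  ovl <- function(R) .area_strip_disc(R, re, -th)     # strip inside disc R
  a_nid <- pi * Rn^2 / 2 - ovl(Rn)
  areas <- switch(scenario_id,
    a = {
      a_scl <- pi * (Rs^2 - Rn^2) / 2 - (ovl(Rs) - ovl(Rn))
      a_tra <- Rci * H - pi * Rs^2 / 2 - (strip_total - ovl(Rs))
      a_cor <- (Rco - Rci) * H
      a_mus <- (D - Rco) * H
      c(electrode = a_elec, plastic = a_plas, nidus = a_nid,
        sclerotic = a_scl, trabecular = a_tra, cortical = a_cor,
        muscle = a_mus)
    },
    b = {
      a_tra <- Rci * H - pi * Rn^2 / 2 - (strip_total - ovl(Rn))
      a_cor <- (Rco - Rci) * H
      a_mus <- (D - Rco) * H
      c(electrode = a_elec, plastic = a_plas, nidus = a_nid,
        trabecular = a_tra, cortical = a_cor, muscle = a_mus)
    },
    c = {
      a_cor <- crx * 2 * chz - pi * Rn^2 / 2 - (re * (chz + th) - ovl(Rn))
      a_mus <- D * H - a_elec - a_plas - a_nid - a_cor
      c(electrode = a_elec, plastic = a_plas, nidus = a_nid,
        cortical = a_cor, muscle = a_mus)
    },
    validation = {
      a_cor <- D * (D - zb) - pi * Rn^2 / 2 - (strip_total - ovl(Rn))
      a_mus <- D * (zb + D)
      c(electrode = a_elec, plastic = a_plas, nidus = a_nid,
        cortical = a_cor, muscle = a_mus)
    })
  stopifnot(abs(sum(areas) - D * H) < 1e-8 * D * H, all(areas > 0))

  ## interface bookkeeping for the mesher
  circles <- switch(scenario_id, a = c(Rn, Rs), b = Rn, c = Rn,
                    validation = Rn)
  r_lines <- switch(scenario_id,
    a = c(re, Rci, Rco), b = c(re, Rci, Rco), c = c(re, crx),
    validation = re)
  z_lines <- switch(scenario_id,
    a = c(-th, th), b = c(-th, th), c = c(-th, th, -chz, chz),
    validation = c(-th, th, zb))

  probes <- NULL
  if (scenario_id == "validation")
    probes <- cbind(r = c(0, 0, 0), z = zb - c(0, 5, 10))

  structure(list(
    scenario_id = scenario_id,
    params = p,
    classify = classify,
    regions = data.frame(label = names(areas), area_mm2 = unname(areas),
                         stringsAsFactors = FALSE),
    circles = circles,
    r_lines = r_lines,
    z_lines = z_lines,
    probe_points = probes,
    bbox = c(r_max = D, z_min = -D, z_max = D),
    electrode = c(radius = re, tip_half = th)
  ), class = "region_geometry")
}

#' @exportS3Method base::print
print.region_geometry <- function(x, ...) {
  cat("Axisymmetric scenario geometry '", x$scenario_id, "'\n", sep = "")
  cat("  domain: r <= ", x$bbox["r_max"], " mm, z in [",
      x$bbox["z_min"], ", ", x$bbox["z_max"], "] mm\n", sep = "")
  cat("  electrode: radius ", x$electrode["radius"], " mm, active tip ",
      2 * x$electrode["tip_half"], " mm\n", sep = "")
  cat("  regions (planar areas, mm^2):\n")
  print(x$regions, row.names = FALSE)
  if (!is.null(x$probe_points)) {
    cat("  probes (r, z) mm:\n")
    print(x$probe_points)
  }
  invisible(x)
}
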