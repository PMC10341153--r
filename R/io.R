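# Plain-text persistence: CSV for curves, tests and recordings (metadata in
# '#'-prefixed header lines), JSON for parameters, designs and results.

write_meta_csv <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]], digits = 15)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_meta_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*:\\s*", "", kv)
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (is.na(num)) val else num
  }
  df <- read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"))
  list(data = df, meta = meta)
}

#' Read and write pressure-radius curves
#'
#' CSV with columns `pressure_mmHg`, `radius_mm` and '#'-prefixed metadata
#' header lines for temperature and prestretch.
#'
#' @param curve a [pr_curve()].
#' @param path file path.
#' @return `write_pr_curve()` returns the path invisibly;
#'   `read_pr_curve()` returns a `pressure_radius_curve`.
#' @export
write_pr_curve <- function(curve, path) {
  stopifnot(inherits(curve, "pressure_radius_curve"))
  write_meta_csv(data.frame(pressure_mmHg = curve$pressure,
                            radius_mm = curve$radius),
                 path,
                 list(temperature_C = attr(curve, "temperature"),
                      prestretch = attr(curve, "prestretch")))
}

#' @rdname write_pr_curve
#' @export
read_pr_curve <- function(path) {
  x <- read_meta_csv(path)
  pr_curve(x$data$pressure_mmHg, x$data$radius_mm,
           T = if (is.null(x$meta$temperature_C)) NA_real_ else x$meta$temperature_C,
           prestretch = if (is.null(x$meta$prestretch)) NA_real_ else x$meta$prestretch)
}

#' Read and write bench recordings
#'
#' CSV with columns `time_s`, `pressure_mmHg`, `flow_mL_s`, `diameter_mm`
#' (optionally `deflection_mm`) plus '#'-prefixed metadata header lines.
#'
#' @param recording a [bench_recording()].
#' @param path file path.
#' @return `write_bench_recording()` returns the path invisibly;
#'   `read_bench_recording()` returns a `bench_recording`.
#' @export
write_bench_recording <- function(recording, path) {
  stopifnot(inherits(recording, "bench_recording"))
  df <- data.frame(time_s = recording$time,
                   pressure_mmHg = recording$pressure,
                   flow_mL_s = recording$flow,
                   diameter_mm = recording$diameter)
  if (!is.null(recording$deflection)) df$deflection_mm <- recording$deflection
  write_meta_csv(df, path,
                 list(temperature_C = attr(recording, "temperature"),
                      prestretch = attr(recording, "prestretch"),
                      span_mm = attr(recording, "span"),
                      n_precond = attr(recording, "n_precond"),
                      n_experimental = attr(recording, "n_experimental")))
}

#' @rdname write_bench_recording
#' @export
read_bench_recording <- function(path) {
  x <- read_meta_csv(path)
  m <- x$meta
  bench_recording(time = x$data$time_s, pressure = x$data$pressure_mmHg,
                  flow = x$data$flow_mL_s, diameter = x$data$diameter_mm,
                  deflection = x$data$deflection_mm,
                  temperature = m$temperature_C %||% 36,
                  prestretch = m$prestretch %||% 1.10,
                  span = m$span_mm %||% 150,
                  n_precond = m$n_precond %||% 10,
                  n_experimental = m$n_experimental %||% 10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write material parameters as JSON
#'
#' Ogden files carry the explicit convention tag
#' `"ogden_2mu_over_alpha_sq"`; files with a different tag are refused
#' rather than silently reinterpreted.
#'
#' @param params an [ogden_params()] or [nitinol_params()] object.
#' @param path file path.
#' @return `write_material_json()` returns the path invisibly;
#'   `read_material_json()` returns the parameter object.
#' @export
write_material_json <- function(params, path) {
  if (inherits(params, "ogden_params")) {
    obj <- list(model = "ogden", convention = "ogden_2mu_over_alpha_sq",
                mu_MPa = params$mu, alpha = params$alpha)
  } else if (inherits(params, "nitinol_params")) {
    obj <- c(list(model = "nitinol_superelastic"), unclass(params))
  } else stop("unsupported parameter object")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_material_json
#' @export
read_material_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$model, "ogden")) {
    if (!identical(obj$convention, "ogden_2mu_over_alpha_sq"))
      stop("unknown Ogden convention tag: ", obj$convention)
    ogden_params(obj$mu_MPa, obj$alpha)
  } else if (identical(obj$model, "nitinol_superelastic")) {
    do.call(nitinol_params,
            obj[setdiff(names(obj), "model")])
  } else stop("unknown material model: ", obj$model)
}

#' Read and write graft assemblies as JSON
#'
#' @param assembly a [graft_assembly()].
#' @param path file path.
#' @return `write_assembly_json()` returns the path invisibly;
#'   `read_assembly_json()` returns a `graft_assembly`.
#' @export
write_assembly_json <- function(assembly, path) {
  stopifnot(inherits(assembly, "graft_assembly"))
  st <- assembly$stent
  fb <- assembly$fabric
  obj <- list(
    stent = list(d = st$d, l = st$l, s = st$s, n = st$n,
                 w = st$w, r = st$r, t = st$t,
                 material = unclass(st$material)),
    fabric = list(D_nominal = fb$D_nominal, h = fb$h,
                  ogden = list(convention = "ogden_2mu_over_alpha_sq",
                               mu_MPa = fb$ogden$mu, alpha = fb$ogden$alpha),
                  smoothing_width = fb$smoothing_width, kappa = fb$kappa,
                  temp_softening = fb$temp_softening, T_ref = fb$T_ref))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_assembly_json
#' @export
read_assembly_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- obj$stent
  mat <- do.call(nitinol_params, as.list(st$material))
  stent <- stent_design(st$d, st$l, st$s, st$n, st$w, st$r, st$t,
                        material = mat)
  fb <- obj$fabric
  if (!identical(fb$ogden$convention, "ogden_2mu_over_alpha_sq"))
    stop("unknown Ogden convention tag in assembly file")
  fabric <- fabric_layer(fb$D_nominal, fb$h,
                         ogden_params(fb$ogden$mu_MPa, fb$ogden$alpha),
                         smoothing_width = fb$smoothing_width,
                         kappa = fb$kappa,
                         temp_softening = fb$temp_softening,
                         T_ref = fb$T_ref)
  graft_assembly(stent, fabric)
}

#' Read and write uniaxial tensile tests
#'
#' CSV with columns `stretch` (or `strain`), `stress_MPa` and optional
#' `time_s`, plus '#'-prefixed metadata headers for temperature and
#' specimen label.
#'
#' @param test a [uniaxial_test()].
#' @param path file path.
#' @return `write_uniaxial_csv()` returns the path invisibly;
#'   `read_uniaxial_csv()` returns a `uniaxial_test`.
#' @export
write_uniaxial_csv <- function(test, path) {
  stopifnot(inherits(test, "uniaxial_test"))
  write_meta_csv(data.frame(stretch = test$stretch, stress_MPa = test$stress),
                 path,
                 list(temperature_C = attr(test, "temperature"),
                      specimen = attr(test, "specimen")))
}

#' @rdname write_uniaxial_csv
#' @export
read_uniaxial_csv <- function(path) {
  x <- read_meta_csv(path)
  stretch <- x$data$stretch
  if (is.null(stretch) && !is.null(x$data$strain)) stretch <- 1 + x$data$strain
  uniaxial_test(stretch = stretch, stress = x$data$stress_MPa,
                temperature = x$meta$temperature_C %||% 21,
                specimen = x$meta$specimen %||% "specimen")
}
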