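#' Species physiology parameters
#'
#' Container for the physiological constants of the toxicokinetic model.
#' Cardiac output scales allometrically with body weight as
#' `QC = QCC * BW^0.74`; a fixed fraction `QfilC` of cardiac output passes
#' into the renal filtrate compartment, whose volume scales linearly with
#' body weight.
#'
#' @param BW Body weight, kg.
#' @param QCC Cardiac output coefficient, L/h per kg^0.74.
#' @param QfilC Fraction of cardiac output filtered into the filtrate
#'   compartment (dimensionless, in (0, 1)).
#' @param VfilC Filtrate compartment volume coefficient, L/kg (in (0, 1)).
#' @return An object of class `physio_params`.
#' @examples
#' physio_params(BW = 70, QCC = 12.5)
#' @export
physio_params <- function(BW = 70, QCC = 12.5, QfilC = 0.15, VfilC = 4e-4) {
  x <- list(BW = BW, QCC = QCC, QfilC = QfilC, VfilC = VfilC)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single positive finite number", call. = FALSE)
    }
  }
  if (QfilC >= 1) stop("`QfilC` must be in (0, 1)", call. = FALSE)
  if (VfilC >= 1) stop("`VfilC` must be in (0, 1)", call. = FALSE)
  structure(x, class = "physio_params")
}

#' Chemical-specific toxicokinetic parameters
#'
#' The eight chemical-specific constants of the three-compartment model
#' with saturable renal resorption.
#'
#' @param bioAv Oral bioavailability fraction (0, 1].
#' @param VCC Central volume of distribution coefficient, L/kg.
#' @param Tmc Maximum resorption rate coefficient, mg/h/kg (scaled by body
#'   weight to `Tm = Tmc * BW` mg/h).
#' @param Kt Resorption affinity constant, mg/L.
#' @param Free Free (protein-unbound) fraction in serum (0, 1].
#' @param k12 Central-to-deep first-order rate, 1/h.
#' @param k21 Deep-to-central first-order rate, 1/h.
#' @param ka Gut-to-central absorption rate, 1/h.
#' @return An object of class `chemical_params`.
#' @examples
#' chemical_params(bioAv = 0.9, VCC = 0.24, Tmc = 1.07, Kt = 0.004,
#'                 Free = 4.5e-3, k12 = 3.3, k21 = 3.4, ka = 132)
#' @export
chemical_params <- function(bioAv, VCC, Tmc, Kt, Free, k12, k21, ka) {
  x <- list(bioAv = bioAv, VCC = VCC, Tmc = Tmc, Kt = Kt, Free = Free,
            k12 = k12, k21 = k21, ka = ka)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("`", nm, "` must be a single non-negative finite number",
           call. = FALSE)
    }
  }
  # Tmc = 0 (no resorption) is a valid limiting case; the others must be > 0
  for (nm in c("bioAv", "VCC", "Kt", "Free", "k12", "k21", "ka")) {
    if (x[[nm]] <= 0) stop("`", nm, "` must be > 0", call. = FALSE)
  }
  if (bioAv > 1) stop("`bioAv` must be <= 1", call. = FALSE)
  if (Free > 1) stop("`Free` must be <= 1", call. = FALSE)
  structure(x, class = "chemical_params")
}

chem_param_names <- function() {
  c("bioAv", "VCC", "Tmc", "Kt", "Free", "k12", "k21", "ka")
}

#' Derive body-weight-scaled rate constants
#'
#' Applies the allometric and linear body-weight scalings of the parameter
#' table: `QC = QCC * BW^0.74` (cardiac output, L/h), `Qfil = QfilC * QC`
#' (filtrate flow, L/h), `Vc = VCC * BW` (central volume, L),
#' `Vfil = VfilC * BW` (filtrate volume, L) and `Tm = Tmc * BW` (maximum
#' resorption rate, mg/h).
#'
#' @param physio A [physio_params()] object.
#' @param chem A [chemical_params()] object.
#' @return A list of class `derived_rates` with elements `QC`, `Qfil`,
#'   `Vc`, `Vfil`, `Tm`.
#' @examples
#' derive_rates(physio_params(BW = 70, QCC = 12.5),
#'              tk_params("pfoa_human")$chemical)
#' @export
derive_rates <- function(physio, chem) {
  stopifnot(inherits(physio, "physio_params"),
            inherits(chem, "chemical_params"))
  QC <- physio$QCC * physio$BW^0.74
  structure(list(
    QC = QC,
    Qfil = physio$QfilC * QC,
    Vc = chem$VCC * physio$BW,
    Vfil = physio$VfilC * physio$BW,
    Tm = chem$Tmc * physio$BW
  ), class = "derived_rates")
}

#' @export
print.physio_params <- function(x, ...) {
  cat("<physio_params>  BW =", x$BW, "kg, QCC =", x$QCC,
      "L/h/kg^0.74, QfilC =", x$QfilC, ", VfilC =", x$VfilC, "L/kg\n")
  invisible(x)
}

#' @export
print.chemical_params <- function(x, ...) {
  cat("<chemical_params>\n")
  print(unlist(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @export
tidy.physio_params <- function(x, ...) {
  tibble::tibble(
    parameter = names(x),
    value = unlist(x, use.names = FALSE),
    unit = c("kg", "L/h/kg^0.74", "-", "L/kg")
  )
}

#' @export
tidy.chemical_params <- function(x, ...) {
  tibble::tibble(
    parameter = names(x),
    value = unlist(x, use.names = FALSE),
    unit = c("-", "L/kg", "mg/h/kg", "mg/L", "-", "1/h", "1/h", "1/h")
  )
}

#' Packaged chemical parameter sets
#'
#' Loads one of the packaged PFAS parameter fixtures (cynomolgus-monkey
#' fits and their human-scaled counterparts for PFOS, PFOA and PFHxS), or
#' any parameter file in the same JSON layout.
#'
#' @param name One of `"pfos_monkey"`, `"pfoa_monkey"`, `"pfhxs_monkey"`,
#'   `"pfos_human"`, `"pfoa_human"`, `"pfhxs_human"`, or a path to a JSON
#'   file with `physio` and `chemical` blocks.
#' @return A list with elements `physio` ([physio_params()]), `chemical`
#'   ([chemical_params()]), and `half_life_years` (the literature serum
#'   half-life used for human scaling; `NA` for animal fits).
#' @examples
#' p <- tk_params("pfoa_human")
#' p$chemical$Tmc
#' @export
tk_params <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  path <- if (file.exists(name)) {
    name
  } else {
    system.file("extdata", "params", paste0(name, ".json"),
                package = "pfastk", mustWork = FALSE)
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown parameter set '", name, "'; packaged sets: ",
         paste(tk_param_sets(), collapse = ", "), call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    physio = do.call(physio_params, as.list(raw$physio)),
    chemical = do.call(chemical_params, as.list(raw$chemical)),
    half_life_years = if (is.null(raw$half_life_years)) NA_real_
                      else raw$half_life_years
  )
}

#' @rdname tk_params
#' @export
tk_param_sets <- function() {
  dir <- system.file("extdata", "params", package = "pfastk")
  sort(sub("\\.json$", "", list.files(dir, pattern = "\\.json$")))
}

#' Write a parameter set to JSON
#'
#' @param params A list with `physio`, `chemical` and optionally
#'   `half_life_years`, as returned by [tk_params()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tk_params <- function(params, path) {
  out <- list(
    physio = unclass(params$physio),
    chemical = unclass(params$chemical),
    half_life_years = params$half_life_years
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
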