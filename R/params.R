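# Biophysical parameter sets.  All constants live in the versioned parameter
# file under inst/extdata; code treats them as data.

.param_cache <- new.env(parent = emptyenv())

#' Load the versioned model constants
#'
#' Reads the package's versioned parameter file holding every biophysical and
#' network constant (membrane properties, Table-style kinetic constants,
#' synaptic and network defaults).
#'
#' @param version integer parameter-file version.
#' @return a nested list mirroring the JSON structure.
#' @export
model_constants <- function(version = 1) {
  key <- paste0("v", version)
  if (!is.null(.param_cache[[key]])) return(.param_cache[[key]])
  path <- system.file("extdata", sprintf("model_params_v%d.json", version),
                      package = "gainprop")
  if (path == "") stop("no parameter file for version ", version)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  .param_cache[[key]] <- p
  p
}

#' Membrane area of the model patch
#'
#' The cell is a membrane patch of fixed radius; injected currents in pA are
#' converted to densities through its area.  The geometry of the "patch" is a
#' convention: a flat disc (`pi r^2`, the default, calibrated against the
#' model's DC landmarks) or a sphere (`4 pi r^2`).
#'
#' @param radius patch radius in micrometres.
#' @param convention `"disc"` or `"sphere"`.
#' @return area in square micrometres.
#' @export
membrane_area <- function(radius = 30, convention = c("disc", "sphere")) {
  convention <- match.arg(convention)
  stopifnot(radius > 0)
  switch(convention, disc = pi * radius^2, sphere = 4 * pi * radius^2)
}

#' Construct a neuron parameter set
#'
#' Builds the single-compartment conductance-based neuron of the modified
#' Mainen type: leak, transient Na (`m^3 h`) and delayed-rectifier K (`n`)
#' currents.  The two named types differ only in the maximal Na conductance:
#' `"GS"` (gain-scaling, g_Na/g_K = 1.5) and `"NGS"` (nongain-scaling,
#' g_Na/g_K = 0.6).
#'
#' @param type `"GS"` or `"NGS"`, selecting the studied conductance ratio.
#' @param g_na,g_k maximal conductance densities (pS/um^2); override the type.
#' @param area_convention patch geometry, see [membrane_area()].
#' @param ... further overrides of membrane constants (`g_leak`, `e_na`,
#'   `e_k`, `e_leak`, `c_m`, `patch_radius`, `spike_threshold`, `refractory`,
#'   `dt`).
#' @return an object of class `neuron_params`.
#' @examples
#' p <- neuron_params("NGS")
#' p$g_na / p$g_k     # 0.6
#' @export
neuron_params <- function(type = c("NGS", "GS"), g_na = NULL, g_k = NULL,
                          area_convention = NULL, ...) {
  type <- match.arg(type)
  const <- model_constants()
  memb <- const$membrane
  over <- list(...)
  unknown <- setdiff(names(over),
                     c("g_leak", "e_na", "e_k", "e_leak", "c_m", "patch_radius",
                       "spike_threshold", "refractory", "dt"))
  if (length(unknown))
    stop("unknown parameter override(s): ", paste(unknown, collapse = ", "))
  memb <- modifyList(memb, over)
  if (is.null(area_convention)) area_convention <- memb$area_convention
  cond <- const$conductances[[type]]
  if (is.null(g_na)) g_na <- cond$g_na
  if (is.null(g_k)) g_k <- cond$g_k
  p <- list(
    type = type,
    g_na = g_na, g_k = g_k, g_leak = memb$g_leak,
    e_na = memb$e_na, e_k = memb$e_k, e_leak = memb$e_leak,
    c_m = memb$c_m,
    patch_radius = memb$patch_radius,
    area_convention = area_convention,
    area = membrane_area(memb$patch_radius, area_convention),
    spike_threshold = memb$spike_threshold,
    refractory = memb$refractory,
    dt = memb$dt,
    kinetics = const$kinetics
  )
  validate_neuron_params(p)
  class(p) <- "neuron_params"
  p
}

validate_neuron_params <- function(p) {
  stopifnot(p$g_na >= 0, p$g_k >= 0, p$g_leak >= 0, p$c_m > 0, p$area > 0,
            p$dt > 0, p$refractory >= 0)
  if (p$g_k > 0 && p$g_na / p$g_k < 0) stop("invalid conductance ratio")
  for (g in c("m", "h", "n")) {
    kin <- p$kinetics[[g]]
    for (r in c("alpha", "beta")) {
      stopifnot(kin[[r]]$amplitude >= 0, kin[[r]]$k > 0)
    }
  }
  invisible(p)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("<neuron_params> type %s  g_Na/g_K = %.2f\n", x$type, x$g_na / x$g_k))
  cat(sprintf("  g_Na %g, g_K %g, g_leak %g pS/um^2; C_m %g uF/cm^2\n",
              x$g_na, x$g_k, x$g_leak, x$c_m))
  cat(sprintf("  E_Na %g, E_K %g, E_leak %g mV; area %.0f um^2 (%s)\n",
              x$e_na, x$e_k, x$e_leak, x$area, x$area_convention))
  invisible(x)
}
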