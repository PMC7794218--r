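# Liquid junction potentials by the generalized Henderson equation.
#
# Relative mobilities are limiting-conductivity values normalised to K+,
# u_i = (lambda_i / z_i^2) / lambda_K, the convention of standard junction
# potential calculators.  Bulky buffer ions (EGTA, HEPES) are treated as
# negligibly mobile and neutral species (glucose) carry no charge, so
# neither contributes to the junction potential; both conventions are
# deliberate and documented in the vignette.

.ion_table <- data.frame(
  ion = c("K", "Na", "Li", "Cs", "Ca", "Mg", "Cl", "gluconate",
          "HCO3", "H2PO4", "SO4", "acetate", "F", "Br", "NO3",
          "EGTA", "HEPES", "glucose", "sucrose"),
  valence = c(1, 1, 1, 1, 2, 2, -1, -1,
              -1, -1, -2, -1, -1, -1, -1,
              -2, -1, 0, 0),
  mobility = c(1.0000, 0.6820, 0.5260, 1.0500, 0.4048, 0.3610, 1.0388, 0.3300,
               0.6054, 0.4490, 0.5442, 0.5561, 0.7540, 1.0630, 0.9720,
               0, 0, 0, 0),
  stringsAsFactors = FALSE
)

#' Limiting relative ion mobilities
#'
#' The bundled mobility table used by [henderson_ljp()]: limiting ionic
#' conductivities at 25 degrees C expressed relative to K+ (per unit charge
#' squared).  EGTA and HEPES are included with zero mobility, neutral
#' species with zero valence.
#'
#' @return Data frame with columns `ion`, `valence`, `mobility`.
#' @export
ion_mobilities <- function() .ion_table

#' Ionic solution composition
#'
#' Expands a named vector of salt/species concentrations into per-ion
#' concentrations using the bundled ion table.  Recognised compounds are
#' dissociated (`NaCl`, `KCl`, `CaCl2`, `MgCl2`, `K-gluconate`,
#' `NaH2PO4`, `NaHCO3`, `K2SO4`); species named directly after an ion
#' (e.g. `"K"`, `"gluconate"`, `"EGTA"`, `"glucose"`) are used as such.
#'
#' @param ... Named concentrations in mM, or a single named numeric vector.
#' @return Object of class `solution_spec`: data frame with `ion`,
#'   `conc_mm`, `valence`, `mobility`.
#' @examples
#' solution_spec(NaCl = 101, CaCl2 = 1, MgCl2 = 4, KCl = 3, glucose = 5,
#'               NaH2PO4 = 1.25, NaHCO3 = 20.7)
#' @export
solution_spec <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.null(names(args)) == FALSE &&
      is.numeric(args[[1]]) && length(args[[1]]) > 1 && !is.null(names(args[[1]]))) {
    conc <- args[[1]]
  } else {
    conc <- unlist(args)
  }
  if (is.null(names(conc)) || any(names(conc) == ""))
    stop("all concentrations must be named", call. = FALSE)
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  salts <- list(
    NaCl = c(Na = 1, Cl = 1), KCl = c(K = 1, Cl = 1),
    CaCl2 = c(Ca = 1, Cl = 2), MgCl2 = c(Mg = 1, Cl = 2),
    `K-gluconate` = c(K = 1, gluconate = 1),
    Kgluconate = c(K = 1, gluconate = 1),
    NaH2PO4 = c(Na = 1, H2PO4 = 1), NaHCO3 = c(Na = 1, HCO3 = 1),
    K2SO4 = c(K = 2, SO4 = 1), `Na-acetate` = c(Na = 1, acetate = 1)
  )
  ions <- numeric(0)
  for (nm in names(conc)) {
    parts <- if (nm %in% names(salts)) {
      salts[[nm]] * conc[[nm]]
    } else if (nm %in% .ion_table$ion) {
      stats::setNames(conc[[nm]], nm)
    } else {
      stop(sprintf("unknown species '%s' (no entry in the ion table)", nm),
           call. = FALSE)
    }
    for (ion in names(parts)) {
      ions[ion] <- (if (ion %in% names(ions)) ions[[ion]] else 0) + parts[[ion]]
    }
  }
  tab <- .ion_table[match(names(ions), .ion_table$ion), ]
  out <- data.frame(ion = names(ions), conc_mm = unname(ions),
                    valence = tab$valence, mobility = tab$mobility,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("solution_spec", "data.frame")
  out
}

#' @export
print.solution_spec <- function(x, ...) {
  cat("<solution_spec> (mM)\n")
  print.data.frame(x)
  invisible(x)
}

#' Liquid junction potential by the generalized Henderson equation
#'
#' Computes the junction potential between the pipette (internal) and bath
#' (external) solutions from limiting relative ion mobilities:
#' \deqn{E = \frac{RT}{F}\,
#'   \frac{\sum_i z_i u_i (c_i^{bath} - c_i^{pip})}
#'        {\sum_i z_i^2 u_i (c_i^{bath} - c_i^{pip})}\,
#'   \ln \frac{\sum_i z_i^2 u_i c_i^{pip}}{\sum_i z_i^2 u_i c_i^{bath}}}
#' The sign convention is the correction convention of whole-cell
#' recording: the returned value (bath potential relative to the pipette)
#' is subtracted from recorded membrane voltages.
#'
#' @param internal,external [solution_spec()] objects for the pipette and
#'   bath solutions.
#' @param temp_c Temperature, degrees C.
#' @return Junction potential, mV.
#' @examples
#' int <- solution_spec(`K-gluconate` = 102, NaCl = 17, EGTA = 0.94,
#'                      HEPES = 8.5, CaCl2 = 0.085, MgCl2 = 1.7)
#' ext <- solution_spec(NaCl = 101, CaCl2 = 1, MgCl2 = 4, KCl = 3,
#'                      glucose = 5, NaH2PO4 = 1.25, NaHCO3 = 20.7)
#' henderson_ljp(int, ext)  # ~13 mV
#' @export
henderson_ljp <- function(internal, external, temp_c = 25) {
  stopifnot(inherits(internal, "solution_spec"),
            inherits(external, "solution_spec"))
  ions <- union(internal$ion, external$ion)
  tab <- .ion_table[match(ions, .ion_table$ion), ]
  if (anyNA(tab$mobility))
    stop("missing mobility entry for: ",
         paste(ions[is.na(tab$mobility)], collapse = ", "), call. = FALSE)
  charged <- tab$valence != 0
  if (!any(tab$ion[charged] %in% internal$ion) ||
      !any(tab$ion[charged] %in% external$ion))
    stop("each solution needs at least one charged species", call. = FALSE)
  cp <- internal$conc_mm[match(ions, internal$ion)]
  cs <- external$conc_mm[match(ions, external$ion)]
  cp[is.na(cp)] <- 0
  cs[is.na(cs)] <- 0
  z <- tab$valence
  u <- tab$mobility
  dlt <- cs - cp
  num <- sum(z * u * dlt)
  den <- sum(z^2 * u * dlt)
  sp <- sum(z^2 * u * cp)
  ss <- sum(z^2 * u * cs)
  rt_f <- 1000 * 8.31446 * (273.15 + temp_c) / 96485.33  # mV
  if (abs(den) < 1e-12 || sp <= 0 || ss <= 0) return(0)
  rt_f * (num / den) * log(sp / ss)
}
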