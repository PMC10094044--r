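# Elemental-composition arithmetic: formula parsing, nominal and
# monoisotopic masses, adduct m/z, and isotope-pattern convolution.

# Isotope masses (u) and abundances pinned from the NIST/CODATA standard
# atomic-weight compilation so results are download-free and version-stable.
# "D" is deuterium as an explicit label (abundance 1 by specification).
ISOTOPE_TABLE <- list(
  H  = data.frame(mass = c(1.00782503207, 2.0141017778), abundance = c(0.999885, 0.000115)),
  D  = data.frame(mass = 2.0141017778, abundance = 1),
  C  = data.frame(mass = c(12, 13.0033548378), abundance = c(0.9893, 0.0107)),
  N  = data.frame(mass = c(14.0030740048, 15.0001088982), abundance = c(0.99636, 0.00364)),
  O  = data.frame(mass = c(15.9949146196, 16.99913170, 17.9991610),
                  abundance = c(0.99757, 0.00038, 0.00205)),
  F  = data.frame(mass = 18.99840322, abundance = 1),
  Na = data.frame(mass = 22.9897692809, abundance = 1),
  P  = data.frame(mass = 30.97376163, abundance = 1),
  S  = data.frame(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
                  abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Cl = data.frame(mass = c(34.96885268, 36.96590259), abundance = c(0.7576, 0.2424)),
  K  = data.frame(mass = c(38.96370668, 39.96399848, 40.96182576),
                  abundance = c(0.932581, 0.000117, 0.067302)),
  Br = data.frame(mass = c(78.9183371, 80.9162906), abundance = c(0.5069, 0.4931)),
  I  = data.frame(mass = 126.904473, abundance = 1)
)

ELECTRON_MASS <- 0.000548579909  # u

most_abundant <- function(sym) {
  tab <- ISOTOPE_TABLE[[sym]]
  if (is.null(tab)) stop_validation("element '%s' is not in the packaged mass table", sym)
  tab$mass[which.max(tab$abundance)]
}

#' Construct an elemental composition
#'
#' @param counts named integer vector of element counts (Hill symbols),
#'   all >= 0, at least one positive
#' @param charge integer charge (sign included), default 0
#' @return object of class `composition`
#' @export
composition <- function(counts, charge = 0L) {
  if (length(counts) == 0L || is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop_validation("'counts' must be a named vector of element counts")
  }
  if (any(counts < 0) || any(counts != trunc(counts))) {
    stop_validation("element counts must be non-negative integers")
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop_validation("composition must contain at least one atom")
  unknown <- setdiff(names(counts), names(ISOTOPE_TABLE))
  if (length(unknown)) {
    stop_validation("unknown element symbol '%s'", unknown[1L])
  }
  if (!is_count(abs(charge))) stop_validation("'charge' must be an integer")
  structure(list(counts = setNames(as.integer(counts), names(counts)),
                 charge = as.integer(charge)),
            class = "composition")
}

#' @export
format.composition <- function(x, ...) {
  body <- paste0(names(x$counts),
                 ifelse(x$counts > 1L, x$counts, ""), collapse = "")
  z <- x$charge
  suffix <- if (z == 0L) "" else
    paste0(if (abs(z) > 1L) abs(z) else "", if (z > 0L) "+" else "-")
  paste0(body, suffix)
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("<composition> %s\n", format(x)))
  invisible(x)
}

#' Parse a Hill-style molecular formula
#'
#' Accepts element symbols with optional counts and an optional trailing
#' charge suffix (`+`, `-`, `2+`, ...), e.g. `"C8H9NO2"` or `"C21H38N+"`.
#'
#' @param text formula string
#' @return a [composition()]
#' @export
#' @examples
#' parse_formula("C8H9NO2")
#' parse_formula("C21H38N+")
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    stop_parse("formula must be a non-empty string")
  }
  s <- text
  charge <- 0L
  m <- regmatches(s, regexec("^(.*?)([0-9]?)([+-])$", s))[[1L]]
  if (length(m)) {
    s <- m[2L]
    mult <- if (nzchar(m[3L])) as.integer(m[3L]) else 1L
    charge <- if (m[4L] == "+") mult else -mult
  }
  counts <- integer()
  pos <- 1L
  while (pos <= nchar(s)) {
    rest <- substr(s, pos, nchar(s))
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1L]]
    if (length(m) == 0L || !nzchar(m[2L]) || !m[2L] %in% names(ISOTOPE_TABLE)) {
      stop_parse("cannot parse formula '%s' at position %d ('%s')",
                 text, pos, substr(s, pos, pos + 1L))
    }
    sym <- m[2L]
    k <- if (nzchar(m[3L])) as.integer(m[3L]) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + k
    pos <- pos + nchar(m[1L])
  }
  composition(counts, charge = charge)
}

as_composition <- function(x) {
  if (inherits(x, "composition")) x else parse_formula(x)
}

#' Nominal (integer) mass of a composition
#'
#' Sum of the integer masses of each element's most abundant isotope
#' (C = 12, H = 1, N = 14, O = 16, Na = 23, K = 39, S = 32, Cl = 35, ...).
#' The charge is ignored: printed fragment assignments are integer-level.
#'
#' @param x a [composition()] or formula string
#' @return integer mass (Da)
#' @export
#' @examples
#' nominal_mass("C7H8")   # 92, the toluene neutral loss
#' nominal_mass("C8H9NO2") # 151, so [M+H]+ appears at m/z 152
nominal_mass <- function(x) {
  comp <- as_composition(x)
  sum(vapply(names(comp$counts),
             function(sym) round(most_abundant(sym)), numeric(1L)) * comp$counts)
}

#' Monoisotopic mass of a composition
#'
#' Sum of the packaged exact masses of each element's most abundant isotope,
#' corrected by the electron mass times the charge (an electron is removed
#' per positive charge).
#'
#' @inheritParams nominal_mass
#' @return monoisotopic mass (Da); for a charged species, the m/z follows by
#'   dividing by |charge|
#' @export
monoisotopic_mass <- function(x) {
  comp <- as_composition(x)
  m <- sum(vapply(names(comp$counts), most_abundant, numeric(1L)) * comp$counts)
  m - comp$charge * ELECTRON_MASS
}

#' Specify an adduct
#'
#' Describes species of the form `[nM + X - Y]^z` such as `[M+Na]+` or
#' `[2M+NH4]+`.
#'
#' @param multiplier M-count `n` (positive integer)
#' @param added composition (or formula string) added, or `NULL`
#' @param removed composition (or formula string) removed, or `NULL`
#' @param charge non-zero integer charge
#' @return object of class `adduct_spec`
#' @export
adduct_spec <- function(multiplier = 1L, added = NULL, removed = NULL,
                        charge = 1L) {
  if (!is_count(multiplier, min = 1)) {
    stop_validation("'multiplier' must be a positive integer")
  }
  if (!is_count(abs(charge), min = 1)) {
    stop_validation("'charge' must be a non-zero integer")
  }
  if (!is.null(added)) added <- as_composition(added)
  if (!is.null(removed)) removed <- as_composition(removed)
  structure(list(multiplier = as.integer(multiplier), added = added,
                 removed = removed, charge = as.integer(charge)),
            class = "adduct_spec")
}

#' Parse an adduct expression
#'
#' Mini-grammar `[nM+X-Y]z+` with any formulas as X and Y, e.g. `"[M+H]+"`,
#' `"[2M+Na]+"`, `"[M+H-H2O]+"`, `"[M]+"`.
#'
#' @param text adduct string
#' @return an [adduct_spec()]
#' @export
parse_adduct <- function(text) {
  m <- regmatches(text, regexec(
    "^\\[([0-9]*)M((?:[+-][A-Za-z0-9]+)*)\\]([0-9]*)([+-])$", text))[[1L]]
  if (length(m) == 0L) stop_parse("cannot parse adduct expression '%s'", text)
  multiplier <- if (nzchar(m[2L])) as.integer(m[2L]) else 1L
  zmag <- if (nzchar(m[4L])) as.integer(m[4L]) else 1L
  charge <- if (m[5L] == "+") zmag else -zmag

  added <- removed <- integer()
  terms <- regmatches(m[3L], gregexpr("[+-][A-Za-z0-9]+", m[3L]))[[1L]]
  for (term in terms) {
    comp <- parse_formula(substring(term, 2L))
    target <- if (substring(term, 1L, 1L) == "+") "added" else "removed"
    cur <- get(target)
    for (sym in names(comp$counts)) {
      cur[sym] <- (if (sym %in% names(cur)) cur[[sym]] else 0L) + comp$counts[[sym]]
    }
    assign(target, cur)
  }
  adduct_spec(multiplier = multiplier,
              added = if (length(added)) composition(added) else NULL,
              removed = if (length(removed)) composition(removed) else NULL,
              charge = charge)
}

#' m/z of an adduct ion
#'
#' Mass of `multiplier * M + added - removed`, divided by |charge|; in
#' monoisotopic mode the electron-mass correction is applied first.
#'
#' @param base base composition M (a [composition()] or formula string)
#' @param adduct an [adduct_spec()] or adduct string such as `"[2M+Na]+"`
#' @param mode `"nominal"` or `"monoisotopic"`
#' @return m/z (Thomson)
#' @export
#' @examples
#' adduct_mz("C8H9NO2", "[2M+Na]+")            # 325 (paracetamol)
#' adduct_mz("C16H21NO2", "[M+Na]+")           # 282 (propranolol)
adduct_mz <- function(base, adduct, mode = c("nominal", "monoisotopic")) {
  mode <- match.arg(mode)
  base <- as_composition(base)
  if (is.character(adduct)) adduct <- parse_adduct(adduct)
  if (!inherits(adduct, "adduct_spec")) {
    stop_validation("'adduct' must be an adduct_spec or adduct string")
  }
  # net element counts must stay non-negative
  net <- adduct$multiplier * to_counts(base)
  if (!is.null(adduct$added)) net <- add_counts(net, to_counts(adduct$added))
  if (!is.null(adduct$removed)) net <- add_counts(net, -to_counts(adduct$removed))
  if (any(net < 0)) {
    stop_validation("adduct removes more '%s' atoms than present",
                    names(net)[which(net < 0)[1L]])
  }
  massf <- if (mode == "nominal") nominal_mass else monoisotopic_mass
  m <- adduct$multiplier * massf(strip_charge(base))
  if (!is.null(adduct$added)) m <- m + massf(adduct$added)
  if (!is.null(adduct$removed)) m <- m - massf(adduct$removed)
  if (mode == "monoisotopic") m <- m - adduct$charge * ELECTRON_MASS
  m / abs(adduct$charge)
}

to_counts <- function(comp) comp$counts
strip_charge <- function(comp) composition(comp$counts, charge = 0L)
add_counts <- function(a, b) {
  syms <- union(names(a), names(b))
  av <- setNames(integer(length(syms)), syms); av[names(a)] <- a
  bv <- setNames(integer(length(syms)), syms); bv[names(b)] <- b
  av + bv
}

#' Theoretical isotope pattern of a composition
#'
#' Convolves the per-element isotope distributions (binomial/multinomial
#' across atom counts), aggregates peaks into 0.01 Da bins, prunes peaks
#' below `threshold` relative to the most intense peak, and normalises.
#' For a charged composition, m/z values are electron-corrected and divided
#' by |charge|.
#'
#' @param x a [composition()] or formula string; at most 1e4 atoms
#' @param threshold prune peaks with relative intensity below this fraction
#'   of the base peak (default 1e-4)
#' @param normalization `"max_100"` (base peak = 100) or `"sum_1"`
#' @return object of class `isotope_pattern`: data frame with columns `mz`
#'   and `intensity`, attribute `normalization`
#' @export
#' @examples
#' isotope_pattern("C", normalization = "sum_1")  # ~ 98.9 : 1.1
isotope_pattern <- function(x, threshold = 1e-4,
                            normalization = c("max_100", "sum_1")) {
  normalization <- match.arg(normalization)
  comp <- as_composition(x)
  if (sum(comp$counts) > 1e4) {
    stop_validation("composition too large for polynomial convolution (> 1e4 atoms)")
  }
  if (!is_number(threshold) || threshold < 0 || threshold >= 1) {
    stop_validation("'threshold' must lie in [0, 1)")
  }

  bin <- 0.01
  dist <- c(`0` = 1)  # named by bin index, values are abundances; mass = idx * bin
  masses <- c(`0` = 0)
  for (sym in names(comp$counts)) {
    tab <- ISOTOPE_TABLE[[sym]]
    for (i in seq_len(comp$counts[[sym]])) {
      dist_new <- numeric(0)
      mass_new <- numeric(0)
      for (j in seq_along(dist)) {
        for (k in seq_len(nrow(tab))) {
          ab <- dist[[j]] * tab$abundance[k]
          if (ab < 1e-14) next
          m <- masses[[j]] + tab$mass[k]
          key <- as.character(round(m / bin))
          if (key %in% names(dist_new)) {
            # abundance-weighted mean mass within a bin
            mass_new[[key]] <- (mass_new[[key]] * dist_new[[key]] + m * ab) /
              (dist_new[[key]] + ab)
            dist_new[[key]] <- dist_new[[key]] + ab
          } else {
            dist_new[[key]] <- ab
            mass_new[[key]] <- m
          }
        }
      }
      dist <- dist_new
      masses <- mass_new
    }
  }

  keep <- dist >= threshold * max(dist)
  dist <- dist[keep]; masses <- masses[keep]
  ord <- order(masses)
  mz <- masses[ord]; ab <- dist[ord]
  if (comp$charge != 0L) {
    mz <- (mz - comp$charge * ELECTRON_MASS) / abs(comp$charge)
  }
  intensity <- if (normalization == "max_100") 100 * ab / max(ab) else ab / sum(ab)
  structure(data.frame(mz = unname(mz), intensity = unname(intensity)),
            normalization = normalization,
            class = c("isotope_pattern", "data.frame"))
}
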