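# Most-abundant-isotope atomic masses (Da). Protonation uses the proton
# mass, not the hydrogen-atom mass; electron mass is otherwise neglected
# (< 0.002 Da, below 4-decimal m/z reporting precision).
ATOMIC_MASS <- c(
  C = 12,
  H = 1.00782503,
  N = 14.00307401,
  O = 15.99491462,
  P = 30.97376163,
  S = 31.97207100,
  Na = 22.98976928,
  K = 38.96370649,
  Cl = 34.96885268
)

PROTON_MASS <- 1.00727646

# Registered singly charged adducts and their m/z deltas relative to the
# neutral monoisotopic mass M.
ADDUCT_REGISTRY <- data.frame(
  name = c("[M+H]+", "[M-H]-", "[M+NH4]+", "[M+CH3COOH-H]-", "[M+H2CO2-H]-"),
  polarity = c("+", "-", "+", "-", "-"),
  # NH4+: N + 4H - e; acetate: + C2H4O2 - proton; formate: + CH2O2 - proton
  delta = c(1.00727646, -1.00727646, 18.03382555, 59.01385292, 44.99820285),
  stringsAsFactors = FALSE
)

#' Parse a compact elemental formula
#'
#' Parses text like `"C6H13N3O3"` into named element counts. Supported
#' elements: C, H, N, O, P, S, Na, K, Cl.
#'
#' @param formula character scalar.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1 || !nzchar(formula)) {
    stop("formula must be a non-empty string")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  els <- sub("[0-9]*$", "", tokens)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                           sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(els, names(ATOMIC_MASS))
  if (length(unknown)) {
    stop("unsupported element(s): ", paste(unknown, collapse = ", "))
  }
  counts <- vapply(split(cnt, els), sum, integer(1))
  counts[counts > 0]
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum of most-abundant-isotope atomic masses over the formula's elements.
#'
#' @param formula compact formula string (e.g. `"C6H13N3O3"`) or a named
#'   count vector from [parse_formula()].
#' @return Monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (length(counts) == 0) stop("empty formula")
  sum(ATOMIC_MASS[names(counts)] * counts)
}

#' Theoretical m/z of a singly charged adduct
#'
#' @param formula neutral elemental formula (string or parsed counts).
#' @param adduct adduct name; one of `[M+H]+`, `[M-H]-`, `[M+NH4]+`,
#'   `[M+CH3COOH-H]-`, `[M+H2CO2-H]-`. Unicode minus signs and embedded
#'   underscores/whitespace in adduct names are normalised.
#' @return Theoretical m/z in Da.
#' @export
adduct_mz <- function(formula, adduct) {
  adduct <- normalize_adduct(adduct)
  i <- match(adduct, ADDUCT_REGISTRY$name)
  if (is.na(i)) stop("unknown adduct: ", adduct)
  monoisotopic_mass(formula) + ADDUCT_REGISTRY$delta[i]
}

# accept typographic variants: unicode minus, explicit charge formatting
normalize_adduct <- function(adduct) {
  a <- gsub("−", "-", adduct)
  a <- gsub("[[:space:]_]", "", a)
  a
}

#' Parts-per-million mass error
#'
#' `(observed - theoretical) / theoretical * 1e6`.
#'
#' @param theoretical theoretical m/z (> 0).
#' @param observed observed m/z.
#' @return Signed mass error in ppm; vectorised.
#' @export
ppm_error <- function(theoretical, observed) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Match observed m/z values against a candidate database
#'
#' Exact-mass annotation: each observed m/z is compared with the theoretical
#' adduct m/z of every candidate; candidates within `tol_ppm` are returned
#' sorted by absolute ppm error. Matches receive annotation confidence
#' level 3 (exact mass only — higher confidence requires MS/MS evidence the
#' caller supplies); observations with no match are flagged level 4
#' ("unknown").
#'
#' @param observed_mz numeric vector of observed m/z values.
#' @param candidates data.frame with columns `name`, `formula`, `adduct`.
#' @param tol_ppm match tolerance in ppm (default 5).
#' @return list, one element per observation: data.frame of matched
#'   candidates (`name`, `formula`, `adduct`, `theoretical_mz`, `ppm`,
#'   `confidence_level`), zero rows when unmatched; attribute
#'   `confidence_level` 3 or 4 per observation on the list.
#' @export
match_features <- function(observed_mz, candidates, tol_ppm = 5) {
  if (tol_ppm <= 0) stop("tol_ppm must be positive")
  theo <- if (nrow(candidates) > 0) {
    mapply(function(f, a) adduct_mz(f, a), candidates$formula,
           candidates$adduct)
  } else numeric(0)
  out <- lapply(observed_mz, function(mz) {
    if (length(theo) == 0) {
      return(data.frame(name = character(0), formula = character(0),
                        adduct = character(0), theoretical_mz = numeric(0),
                        ppm = numeric(0), confidence_level = integer(0)))
    }
    ppm <- ppm_error(theo, mz)
    hit <- which(abs(ppm) <= tol_ppm)
    hit <- hit[order(abs(ppm[hit]))]
    data.frame(name = candidates$name[hit],
               formula = candidates$formula[hit],
               adduct = candidates$adduct[hit],
               theoretical_mz = theo[hit], ppm = ppm[hit],
               confidence_level = rep(3L, length(hit)), row.names = NULL)
  })
  attr(out, "confidence_level") <- vapply(out, function(d) {
    if (nrow(d) > 0) 3L else 4L
  }, integer(1))
  out
}

#' Load a reference annotation table
#'
#' Reads a tab-separated annotation table (columns `annotation`, `formula`,
#' `adduct`, `mz_experimental`, plus free metadata columns). Two curated
#' tables from the deposited TKO serum study (Metabolomics Workbench
#' ST002067) ship with the package: `"hilic_metabolites"` (14 polar
#' metabolites, negative mode) and `"lipid_panel"` (the 22-lipid
#' discriminant panel).
#'
#' @param which built-in table name, or a path to a compatible TSV.
#' @return data.frame.
#' @export
reference_annotations <- function(which = c("hilic_metabolites", "lipid_panel")) {
  path <- if (file.exists(which[1])) {
    which[1]
  } else {
    which <- match.arg(which)
    system.file("extdata", paste0(which, ".tsv"), package = "metatrack",
                mustWork = TRUE)
  }
  utils::read.delim(path, check.names = FALSE)
}
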