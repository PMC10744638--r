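# Isotopologue arithmetic: molecular formulas, natural-abundance tables, exact
# mass-shift distributions and the hypergeometric fragment-retention model used
# to render the 13C2-THC-COOH isobaric interference on the HHC-COOH channels.

# Elements the formula parser accepts. Counts for elements without an entry in
# the isotope table are treated as mono-isotopic (shift 0 with probability 1).
.known_elements <- c(
  "C", "H", "N", "O", "S", "P", "F", "Cl", "Br", "I", "Si", "Se", "B", "Na", "K"
)

#' Parse a molecular formula string
#'
#' Parses an element-count string such as `"C21H28O4"` into a named integer
#' vector of element counts. Hill order is not required; element order is
#' preserved so that [format_formula()] round-trips the input exactly.
#'
#' @param text A single formula string, e.g. `"C21H30O4"` (HHC-COOH).
#'
#' @return A named integer vector of class `molecular_formula`.
#' @export
#' @examples
#' parse_formula("C21H28O4") # THC-COOH
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(text)) stop("empty formula string", call. = FALSE)
  matches <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(nchar(matches)) != nchar(text)) {
    bad <- substr(gsub(paste(vapply(matches, function(m) {
      gsub("([][{}()*+?.\\^$|])", "\\\\\\1", m)
    }, ""), collapse = "|"), "", text), 1, 8)
    stop("malformed formula string near '", bad, "'", call. = FALSE)
  }
  elements <- sub("[0-9]*$", "", matches)
  counts <- as.integer(ifelse(grepl("[0-9]+$", matches),
    sub("^[A-Za-z]+", "", matches), "1"
  ))
  unknown <- setdiff(elements, .known_elements)
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(elements)) {
    counts <- vapply(split(counts, elements)[unique(elements)], sum, integer(1))
    elements <- unique(elements)
  }
  if (all(counts == 0L)) stop("formula has no atoms", call. = FALSE)
  structure(stats::setNames(counts, elements), class = "molecular_formula")
}

#' Serialize a molecular formula
#'
#' @param x A `molecular_formula` (or named integer vector).
#' @param ... Unused.
#' @return A formula string; counts of one are omitted, matching the
#'   conventional notation so `parse_formula()` round-trips.
#' @export
format_formula <- function(x, ...) {
  x <- x[x > 0]
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
format.molecular_formula <- function(x, ...) format_formula(x, ...)

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Natural-abundance isotope table
#'
#' Per element, the probability of each integer mass shift (in Da, relative to
#' the lightest isotope) for a single atom. Defaults are the standard natural
#' abundances: 13C 0.0107, 2H 0.000115, 15N 0.00364, 17O 0.00038, 18O 0.00205,
#' and the sulfur isotopes. All abundances are configurable so that closed-form
#' oracle values can be reproduced exactly.
#'
#' @param overrides Optional named list replacing per-element shift-probability
#'   vectors; each element is a numeric vector `p` with `p[k]` the probability
#'   of shift `k - 1`, summing to 1.
#'
#' @return A named list of numeric vectors of class `isotope_table`.
#' @export
#' @examples
#' default_isotope_table(overrides = list(C = c(0.5, 0.5)))
default_isotope_table <- function(overrides = NULL) {
  tab <- list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), !is.null(names(overrides)))
    tab[names(overrides)] <- overrides
  }
  for (el in names(tab)) {
    p <- tab[[el]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop("abundances for ", el, " must be non-negative and sum to 1",
        call. = FALSE
      )
    }
  }
  structure(tab, class = "isotope_table")
}

#' Read / write an isotope table as structured text
#'
#' The on-disk format is YAML: one key per element, value a list of
#' `{shift, abundance}` pairs.
#'
#' @param path File path.
#' @return `read_isotope_table()` returns an `isotope_table`.
#' @export
read_isotope_table <- function(path) {
  raw <- yaml::read_yaml(path)
  tab <- lapply(raw, function(entries) {
    shifts <- vapply(entries, `[[`, numeric(1), "shift")
    ab <- vapply(entries, `[[`, numeric(1), "abundance")
    p <- numeric(max(shifts) + 1)
    p[shifts + 1] <- ab
    p
  })
  default_isotope_table(overrides = tab)[names(tab)]
}

#' @rdname read_isotope_table
#' @param table An `isotope_table`.
#' @export
write_isotope_table <- function(table, path) {
  out <- lapply(unclass(table), function(p) {
    keep <- which(p > 0 | seq_along(p) == 1L)
    lapply(keep, function(i) list(shift = i - 1L, abundance = p[i]))
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

# Truncated convolution of two shift-probability vectors (index 1 = shift 0).
conv_trunc <- function(a, b, len) {
  out <- numeric(len)
  for (i in seq_len(min(length(a), len))) {
    if (a[i] == 0) next
    j <- seq_len(min(len - i + 1L, length(b)))
    out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
  }
  out
}

# n-fold convolution power of a single-atom distribution, truncated.
conv_power <- function(p, n, len) {
  out <- c(1, numeric(len - 1L))
  base <- p
  while (n > 0L) {
    if (n %% 2L == 1L) out <- conv_trunc(out, base, len)
    base <- conv_trunc(base, base, len)
    n <- n %/% 2L
  }
  out
}

#' Exact isotopologue mass-shift distribution
#'
#' Probability of each integer (nominal) mass shift for a molecular formula,
#' computed by exact convolution of per-element multinomial single-atom
#' distributions -- no Gaussian or Poisson approximation. Probabilities beyond
#' `max_shift` are not returned, so the result may sum to slightly less than 1;
#' the remainder is the mass in higher shifts.
#'
#' @param formula A `molecular_formula` or formula string.
#' @param isotopes An `isotope_table`; defaults to natural abundances.
#' @param max_shift Largest mass shift to report (non-negative integer).
#' @param carbon_only If `TRUE`, only carbon contributes heavy isotopes
#'   (all other elements treated as mono-isotopic); used for closed-form
#'   binomial cross-checks.
#'
#' @return A named numeric vector of class `isotopologue_distribution`,
#'   names `"0" ... max_shift`.
#' @export
#' @examples
#' isotopologue_distribution("C21H28O4", max_shift = 2)
isotopologue_distribution <- function(formula,
                                      isotopes = default_isotope_table(),
                                      max_shift = 4L,
                                      carbon_only = FALSE) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(max_shift >= 0L)
  counts <- unclass(formula)
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("empty formula", call. = FALSE)
  len <- as.integer(max_shift) + 1L
  out <- c(1, numeric(len - 1L))
  for (el in names(counts)) {
    p <- if (carbon_only && el != "C") 1 else isotopes[[el]]
    if (is.null(p)) p <- 1 # elements absent from the table: mono-isotopic
    out <- conv_trunc(out, conv_power(p, counts[[el]], len), len)
  }
  structure(stats::setNames(out, 0:max_shift),
    class = "isotopologue_distribution",
    formula = format_formula(formula)
  )
}

#' @export
print.isotopologue_distribution <- function(x, ...) {
  cat("<isotopologue_distribution> ", attr(x, "formula"), "\n", sep = "")
  print(unclass(structure(x, formula = NULL)), ...)
  invisible(x)
}

#' Tidy an isotopologue distribution
#'
#' @param x An `isotopologue_distribution`.
#' @param ... Unused.
#' @return A tibble with columns `shift` and `probability`.
#' @export
tidy.isotopologue_distribution <- function(x, ...) {
  tibble::tibble(
    formula = attr(x, "formula"),
    shift = as.integer(names(x)),
    probability = as.numeric(x)
  )
}

#' Probability that heavy labels avoid an MRM fragment
#'
#' Under uniform-random placement of `n_labels` heavy atoms on the
#' `total_carbons` carbon skeleton, the probability that all labels fall
#' outside a fragment retaining `fragment_carbons` carbons -- i.e. the
#' probability that a labelled precursor still yields product signal at the
#' unlabelled fragment m/z:
#' `choose(total - fragment, n) / choose(total, n)`.
#'
#' @param total_carbons Carbons in the precursor.
#' @param fragment_carbons Carbons retained in the product ion.
#' @param n_labels Number of heavy labels on the precursor.
#'
#' @return A probability in `[0, 1]`.
#' @export
#' @examples
#' fragment_label_avoidance(21, 14, 2) # 21/210 = 0.1
fragment_label_avoidance <- function(total_carbons, fragment_carbons, n_labels) {
  stopifnot(
    length(total_carbons) == 1, length(fragment_carbons) == 1,
    length(n_labels) == 1
  )
  if (fragment_carbons < 0 || fragment_carbons > total_carbons ||
    n_labels < 0 || n_labels > total_carbons || total_carbons < 0) {
    stop("combinatorially impossible arguments: need 0 <= fragment_carbons <= ",
      "total_carbons and 0 <= n_labels <= total_carbons",
      call. = FALSE
    )
  }
  if (n_labels == 0 || fragment_carbons == 0) {
    return(1)
  }
  choose(total_carbons - fragment_carbons, n_labels) /
    choose(total_carbons, n_labels)
}

#' Expected isobaric interference peak area
#'
#' Area contributed by a heavy isotopologue of a parent compound to a channel
#' monitoring the unlabelled product m/z at the shifted precursor m/z (e.g.
#' 13C2-THC-COOH seen on the HHC-COOH 347.22 channels). The parent area is
#' scaled by the probability of the isotopologue and the probability that the
#' labels avoid the product fragment:
#' `parent_area * P(shift) * P(labels outside fragment)`.
#'
#' Treats all `shift` heavy atoms as carbon labels when evaluating fragment
#' retention; contributions where part of the shift sits on O or H are small at
#' natural abundance and fragment retention for them is not better constrained.
#'
#' @param parent_area Integrated parent peak area (counts), `>= 0`.
#' @param parent_formula Parent molecular formula (object or string).
#' @param shift Nominal mass shift of the interfering isotopologue (default 2).
#' @param fragment_carbons Carbons retained in the monitored product ion.
#' @param isotopes An `isotope_table`.
#' @param carbon_only Restrict the shift probability to carbon isotopes.
#'
#' @return Expected interference area (same units as `parent_area`).
#' @export
#' @examples
#' interference_area(1e6, "C21H28O4", shift = 2, fragment_carbons = 14)
interference_area <- function(parent_area, parent_formula, shift = 2L,
                              fragment_carbons,
                              isotopes = default_isotope_table(),
                              carbon_only = FALSE) {
  stopifnot(parent_area >= 0, shift >= 0)
  if (is.character(parent_formula)) parent_formula <- parse_formula(parent_formula)
  p_shift <- isotopologue_distribution(parent_formula,
    isotopes = isotopes,
    max_shift = shift, carbon_only = carbon_only
  )[[as.character(shift)]]
  p_avoid <- fragment_label_avoidance(
    unclass(parent_formula)[["C"]], fragment_carbons, shift
  )
  parent_area * p_shift * p_avoid
}
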