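#' Parse fatty-acid shorthand nomenclature
#'
#' Lipidology shorthand writes a fatty acid as `carbons:double_bonds` followed,
#' for unsaturated acids, by the position of the first double bond counted from
#' the methyl end (`omega` family). Published tables mix several spellings of
#' the family suffix; all of these are accepted and treated as identical:
#' `"20:5ω3"`, `"20:5ω-3"`, `"20:5ω − 3"`, `"20:5n-3"`,
#' `"20:5w3"`.
#'
#' @param name character vector of shorthand names.
#' @return a data.frame with one row per input name and columns
#'   `name` (input), `canonical` (normalized `C:Dn-N` spelling, e.g.
#'   `"20:5n-3"`; saturated acids stay `"16:0"`), `carbons`, `double_bonds`
#'   (integer) and `family` (one of `"n-3"`, `"n-6"`, `"n-7"`, `"n-9"`,
#'   `"saturated"`).
#' @details A name with no family suffix must have zero double bonds
#'   (saturated); a suffixed name must have at least one. Monounsaturated and
#'   polyunsaturated acids keep their omega family; class membership
#'   (SAT/MUFA/PUFA) is derived from `double_bonds`, see [class_sums()].
#' @examples
#' parse_fa_name(c("16:0", "18:1ω9", "22:6ω3", "20:4n-6"))
#' @export
parse_fa_name <- function(name) {
  if (!is.character(name) || length(name) == 0L) {
    stop("`name` must be a non-empty character vector", call. = FALSE)
  }
  out <- lapply(name, parse_fa_name_one)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# accepted family spellings, normalized before matching:
#   omega (U+03C9), w, n; optional separator "-", hyphen/minus variants,
#   optional spaces ("ω − 3")
parse_fa_name_one <- function(nm) {
  if (is.na(nm) || !nzchar(trimws(nm))) {
    stop("malformed fatty-acid name: empty token", call. = FALSE)
  }
  x <- trimws(nm)
  # unify minus/hyphen/dash variants and strip internal spaces
  x <- gsub("[−‐–]", "-", x)
  x <- gsub("\\s+", "", x)
  m <- regexec("^([0-9]+):([0-9]+)(?:(ω|n|w)-?([0-9]+))?$", x)
  parts <- regmatches(x, m)[[1]]
  if (length(parts) == 0L) {
    stop(sprintf("malformed fatty-acid name: '%s'", nm), call. = FALSE)
  }
  carbons <- as.integer(parts[2])
  dbl <- as.integer(parts[3])
  has_family <- nzchar(parts[4])
  if (carbons < 2L) {
    stop(sprintf("malformed fatty-acid name: '%s' (carbons < 2)", nm),
         call. = FALSE)
  }
  if (has_family) {
    n_pos <- as.integer(parts[5])
    if (dbl == 0L) {
      stop(sprintf("malformed fatty-acid name: '%s' (omega family given for a saturated acid)", nm),
           call. = FALSE)
    }
    family <- paste0("n-", n_pos)
    canonical <- sprintf("%d:%d%s", carbons, dbl, family)
  } else {
    if (dbl != 0L) {
      stop(sprintf("malformed fatty-acid name: '%s' (unsaturated acid needs an omega family)", nm),
           call. = FALSE)
    }
    family <- "saturated"
    canonical <- sprintf("%d:%d", carbons, dbl)
  }
  data.frame(name = nm, canonical = canonical, carbons = carbons,
             double_bonds = dbl, family = family, stringsAsFactors = FALSE)
}

#' Normalize fatty-acid names to the canonical spelling
#'
#' @param name character vector of shorthand names in any accepted dialect.
#' @return character vector of canonical names (`"20:5n-3"` style).
#' @export
canonical_fa_name <- function(name) parse_fa_name(name)$canonical
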