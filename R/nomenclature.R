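#' Lipid class vocabulary
#'
#' Reads the controlled vocabulary of lipid class codes shipped with the
#' package (or a user-supplied TSV with the same columns). Each class code
#' maps to exactly one of the five lipid categories and carries the number
#' of esterified chains expected at the molecular-species level.
#'
#' @param path Path to a tab-separated vocabulary file with columns
#'   `class_code`, `category`, `n_chains`. Defaults to the vocabulary
#'   shipped in `inst/extdata/lipid_classes.tsv`.
#' @return A data frame with columns `class_code` (character), `category`
#'   (character, one of glycerolipid, glycerophospholipid, sphingolipid,
#'   sterol lipid, prenol lipid) and `n_chains` (integer).
#' @examples
#' head(lipid_vocabulary())
#' @export
lipid_vocabulary <- function(path = system.file("extdata", "lipid_classes.tsv",
                                                package = "lipidflux")) {
  voc <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("class_code", "category", "n_chains") %in% names(voc)))
  categories <- c("glycerolipid", "glycerophospholipid", "sphingolipid",
                  "sterol lipid", "prenol lipid")
  if (!all(voc$category %in% categories)) {
    stop("vocabulary contains categories outside the five lipid categories")
  }
  if (anyDuplicated(voc$class_code)) {
    stop("vocabulary class codes must be unique")
  }
  voc$n_chains <- as.integer(voc$n_chains)
  voc
}

condition_error <- function(message, class) {
  stop(structure(class = c(class, "lipidflux_error", "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}

#' Construct a fatty acyl
#'
#' A fatty acyl is the `C:D` unit of shorthand nomenclature: total carbons
#' and total double-bond equivalents of one chain. Chains with fewer than
#' two carbons or chemically impossible unsaturation (more than one double
#' bond per two carbons) are rejected.
#'
#' @param carbons Integer chain length, at least 2.
#' @param double_bonds Integer double-bond count, at least 0 and at most
#'   `carbons / 2`.
#' @return An object of class `fatty_acyl`.
#' @examples
#' fatty_acyl(16, 4)   # hexadecatetraenoic acid, 16:4
#' @export
fatty_acyl <- function(carbons, double_bonds) {
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  if (length(carbons) != 1L || length(double_bonds) != 1L ||
      is.na(carbons) || is.na(double_bonds)) {
    condition_error("carbons and double_bonds must be single integers",
                    "lipidflux_parse_error")
  }
  if (carbons < 2L) {
    condition_error("a fatty acyl needs at least 2 carbons",
                    "lipidflux_parse_error")
  }
  if (double_bonds < 0L || double_bonds > carbons / 2) {
    condition_error(sprintf(
      "impossible unsaturation %d:%d (double bonds must be in [0, carbons/2])",
      carbons, double_bonds), "lipidflux_parse_error")
  }
  structure(list(carbons = carbons, double_bonds = double_bonds),
            class = "fatty_acyl")
}

#' @export
format.fatty_acyl <- function(x, ...) sprintf("%d:%d", x$carbons, x$double_bonds)

#' @export
print.fatty_acyl <- function(x, ...) {
  cat("<fatty acyl>", format(x), "\n")
  invisible(x)
}

parse_acyl_token <- function(token) {
  if (grepl("[OdtePe]", token) || grepl("-", token, fixed = TRUE)) {
    condition_error(sprintf(
      "'%s': oxidized/ether/modified chains are outside the accepted grammar",
      token), "lipidflux_parse_error")
  }
  if (!grepl("^[0-9]+:[0-9]+$", token)) {
    condition_error(sprintf("malformed composition token '%s' (expected C:D)",
                            token), "lipidflux_parse_error")
  }
  parts <- as.integer(strsplit(token, ":", fixed = TRUE)[[1L]])
  fatty_acyl(parts[1L], parts[2L])
}

#' Parse a lipid shorthand name
#'
#' Parses shorthand of the form `CLASS C:D` (sum composition, chains
#' unresolved) or `CLASS C1:D1_C2:D2[...]` (molecular-species level, the
#' underscore separator denoting unknown sn-position). Class codes come from
#' the controlled vocabulary; the chain count at the molecular-species level
#' must match the class (3 for TG, 2 for DG/PC/PE/PA/MGDG/DGDG/..., 1 for
#' LPC/...). Slash-separated names (which would claim sn-position knowledge)
#' and oxidized or ether chains are rejected with specific errors.
#'
#' @param name A single shorthand name, e.g. `"TG 16:0_18:2_18:3"` or
#'   `"TG 54:7"`.
#' @param vocabulary Class vocabulary as returned by [lipid_vocabulary()].
#' @return An object of class `lipid_species` with fields `class_code`,
#'   `category`, `chains` (integer matrix with columns `carbons`,
#'   `double_bonds`; zero rows at sum-composition level), `sum_carbons`,
#'   `sum_double_bonds` and `level` (`"molecular_species"` or
#'   `"sum_composition"`).
#' @examples
#' sp <- parse_shorthand("TG 16:3_16:4_18:2")
#' sp$sum_carbons       # 50
#' sp$sum_double_bonds  # 9
#' parse_shorthand("TG 54:7")$level
#' @export
parse_shorthand <- function(name, vocabulary = lipid_vocabulary()) {
  if (length(name) != 1L || !is.character(name) || is.na(name)) {
    condition_error("name must be a single character string",
                    "lipidflux_parse_error")
  }
  name <- trimws(name)
  if (grepl("/", name, fixed = TRUE)) {
    condition_error(paste0(
      "'", name, "': slash-separated chains imply known sn-position, which ",
      "this nomenclature level does not support; use '_' separators"),
      "lipidflux_parse_error")
  }
  m <- regmatches(name, regexec("^(\\S+)\\s+(\\S+)$", name))[[1L]]
  if (length(m) != 3L) {
    condition_error(sprintf(
      "'%s' does not match the grammar 'CLASS composition'", name),
      "lipidflux_parse_error")
  }
  class_code <- m[2L]
  composition <- m[3L]
  row <- match(class_code, vocabulary$class_code)
  if (is.na(row)) {
    condition_error(sprintf("unknown lipid class token '%s'", class_code),
                    "lipidflux_vocabulary_error")
  }
  tokens <- strsplit(composition, "_", fixed = TRUE)[[1L]]
  if (length(tokens) == 0L || any(!nzchar(tokens))) {
    condition_error(sprintf("malformed composition '%s'", composition),
                    "lipidflux_parse_error")
  }
  acyls <- lapply(tokens, parse_acyl_token)
  n_expected <- vocabulary$n_chains[row]
  if (length(acyls) == 1L && n_expected != 1L) {
    # single C:D token for a multi-chain class is a sum composition
    level <- "sum_composition"
    chains <- matrix(integer(0), ncol = 2L,
                     dimnames = list(NULL, c("carbons", "double_bonds")))
    sum_carbons <- acyls[[1L]]$carbons
    sum_double_bonds <- acyls[[1L]]$double_bonds
  } else {
    if (length(acyls) != n_expected) {
      condition_error(sprintf(
        "class %s expects %d chains at the molecular-species level, got %d",
        class_code, n_expected, length(acyls)), "lipidflux_structure_error")
    }
    level <- "molecular_species"
    chains <- cbind(carbons = vapply(acyls, `[[`, integer(1L), "carbons"),
                    double_bonds = vapply(acyls, `[[`, integer(1L),
                                          "double_bonds"))
    sum_carbons <- sum(chains[, "carbons"])
    sum_double_bonds <- sum(chains[, "double_bonds"])
  }
  structure(list(class_code = class_code,
                 category = vocabulary$category[row],
                 chains = chains,
                 sum_carbons = as.integer(sum_carbons),
                 sum_double_bonds = as.integer(sum_double_bonds),
                 level = level),
            class = "lipid_species")
}

#' Format a lipid species canonically
#'
#' Emits the canonical shorthand for a species: chains sorted by
#' non-decreasing (carbons, double bonds) — the order is informationless
#' because sn-position is unknown — joined with underscores. Round-trips
#' with [parse_shorthand()].
#'
#' @param species A `lipid_species` object.
#' @return A single character string.
#' @examples
#' format_shorthand(parse_shorthand("TG 18:2_16:0_18:3"))  # "TG 16:0_18:2_18:3"
#' @export
format_shorthand <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  if (species$level == "sum_composition") {
    return(sprintf("%s %d:%d", species$class_code,
                   species$sum_carbons, species$sum_double_bonds))
  }
  ch <- species$chains
  ord <- order(ch[, "carbons"], ch[, "double_bonds"])
  ch <- ch[ord, , drop = FALSE]
  paste0(species$class_code, " ",
         paste(sprintf("%d:%d", ch[, "carbons"], ch[, "double_bonds"]),
               collapse = "_"))
}

#' @export
format.lipid_species <- function(x, ...) format_shorthand(x)

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid species> %s  [%s, %s, sum %d:%d]\n",
              format_shorthand(x), x$category, x$level,
              x$sum_carbons, x$sum_double_bonds))
  invisible(x)
}

#' Order-insensitive species equality
#'
#' Two species are equal when their canonical shorthands coincide; chain
#' order never matters because sn-position is unresolved.
#'
#' @param a,b `lipid_species` objects.
#' @return Logical scalar.
#' @export
species_equal <- function(a, b) {
  identical(format_shorthand(a), format_shorthand(b))
}

#' Does a species contain a given fatty acyl?
#'
#' Defined only at the molecular-species level (sum compositions carry no
#' chain information and raise an undefined-query error).
#'
#' @param species A `lipid_species` at level `molecular_species`.
#' @param acyl A [fatty_acyl()] (or a `"C:D"` string).
#' @return A list with `contains` (logical) and `multiplicity` (integer
#'   number of chains equal to `acyl`).
#' @examples
#' contains_acyl(parse_shorthand("TG 16:0_18:2_18:2"), fatty_acyl(18, 2))
#' @export
contains_acyl <- function(species, acyl) {
  stopifnot(inherits(species, "lipid_species"))
  if (is.character(acyl)) acyl <- parse_acyl_token(acyl)
  stopifnot(inherits(acyl, "fatty_acyl"))
  if (species$level != "molecular_species") {
    condition_error(sprintf(
      "acyl membership is undefined for sum-composition species '%s'",
      format_shorthand(species)), "lipidflux_undefined_query_error")
  }
  hits <- species$chains[, "carbons"] == acyl$carbons &
    species$chains[, "double_bonds"] == acyl$double_bonds
  list(contains = any(hits), multiplicity = as.integer(sum(hits)))
}

#' Canonicalize a vector of shorthand names
#'
#' Parses and re-formats each name; used to merge adduct rows of the same
#' species written in different chain orders.
#'
#' @param names Character vector of shorthand names.
#' @param vocabulary Class vocabulary.
#' @return Character vector of canonical names.
#' @export
canonical_names <- function(names, vocabulary = lipid_vocabulary()) {
  vapply(names, function(nm) format_shorthand(parse_shorthand(nm, vocabulary)),
         character(1L), USE.NAMES = FALSE)
}

#' Parse many names into a species table
#'
#' @param names Character vector of (canonical or raw) shorthand names.
#' @param vocabulary Class vocabulary.
#' @return Data frame with one row per name: `name` (canonical),
#'   `class_code`, `category`, `level`, `sum_carbons`, `sum_double_bonds`,
#'   and a list column `chains` of integer matrices.
#' @export
species_table <- function(names, vocabulary = lipid_vocabulary()) {
  parsed <- lapply(names, parse_shorthand, vocabulary = vocabulary)
  data.frame(
    name = vapply(parsed, format_shorthand, character(1L)),
    class_code = vapply(parsed, `[[`, character(1L), "class_code"),
    category = vapply(parsed, `[[`, character(1L), "category"),
    level = vapply(parsed, `[[`, character(1L), "level"),
    sum_carbons = vapply(parsed, `[[`, integer(1L), "sum_carbons"),
    sum_double_bonds = vapply(parsed, `[[`, integer(1L), "sum_double_bonds"),
    chains = I(lapply(parsed, `[[`, "chains")),
    stringsAsFactors = FALSE
  )
}
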