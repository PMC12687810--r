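# Shorthand lipid nomenclature: parsing, parity, canonical keys.
#
# The grammar covered here is the common "CLASS(C:D_C:D)" shorthand used for
# glycerophospholipids, sphingolipids and glycerolipids, e.g. "LPG(13:0)",
# "PG(15:0_18:1-d7)", "TG(15:0_18:1-d7_15:0)", "cholesterol(d7)".  Chain
# separators "_" (sn-position unknown) and "/" (sn-position known) are
# accepted and treated identically: downstream identity and parity never use
# sn-position.  Ether/plasmalogen ("O-", "P-") and sphingoid hydroxylation
# ("d", "t") prefixes are retained as annotations; parity is defined on
# carbon counts alone.

# expected number of acyl/alkyl chains when a species of that class is fully
# chain-resolved; used to tell a single sum-composition descriptor apart from
# a resolved mono-acyl species
.CLASS_CHAINS <- c(
  PC = 2L, PE = 2L, PS = 2L, PG = 2L, PI = 2L, PA = 2L,
  LPC = 1L, LPE = 1L, LPS = 1L, LPG = 1L, LPI = 1L, LPA = 1L,
  SM = 2L, SL = 2L, Cer = 2L, HexCer = 2L,
  TG = 3L, DG = 2L, MG = 1L, CE = 1L, FA = 1L,
  cholesterol = 0L
)

.CLASS_ALIASES <- c(
  "cholesteryl ester" = "CE",
  "CHOLESTEROL" = "cholesterol",
  "CER" = "Cer"
)

#' Lipid class vocabulary
#'
#' The built-in class vocabulary maps a shorthand class code to the number of
#' acyl chains a fully chain-resolved species of that class carries.  The
#' vocabulary can be extended at parse time; unknown class codes never abort
#' a parse (they yield `lipid_class = "other"`).
#'
#' @return Named integer vector: class code -> expected chain count.
#' @export
lipid_class_vocabulary <- function() {
  .CLASS_CHAINS
}

# parse one chain descriptor token such as "18:1", "O-16:0", "d18:1-d7"
.parse_chain_token <- function(token, name) {
  m <- regmatches(
    token,
    regexec("^(O-|P-)?([dt])?([0-9]+):([0-9]+)(?:-d([0-9]+))?$", token)
  )[[1L]]
  if (length(m) == 0L) {
    .stopf("malformed chain descriptor '%s' in lipid name '%s'", token, name)
  }
  carbons <- as.integer(m[4L])
  dbl <- as.integer(m[5L])
  if (carbons < 1L) {
    .stopf("chain carbon count must be >= 1 in '%s' ('%s')", token, name)
  }
  if (dbl > carbons) {
    .stopf(
      "double-bond count exceeds carbon count in '%s' ('%s')", token, name
    )
  }
  list(
    carbons = carbons,
    double_bonds = dbl,
    ether_prefix = if (nzchar(m[2L])) sub("-$", "", m[2L]) else NA_character_,
    hydroxyl_prefix = if (nzchar(m[3L])) m[3L] else NA_character_,
    isotope_label = if (nzchar(m[6L])) paste0("d", m[6L]) else NA_character_
  )
}

.render_chain <- function(ch) {
  paste0(
    ifelse(is.na(ch$ether_prefix), "", paste0(ch$ether_prefix, "-")),
    ifelse(is.na(ch$hydroxyl_prefix), "", ch$hydroxyl_prefix),
    ch$carbons, ":", ch$double_bonds,
    ifelse(is.na(ch$isotope_label), "", paste0("-", ch$isotope_label))
  )
}

#' Parse a shorthand lipid name
#'
#' Parses names such as `"LPG(13:0)"`, `"PG(15:0_18:1-d7)"` or
#' `"cholesterol(d7)"` into a structured `lipid_species` object.  A species
#' is *chain-resolved* when the number of chain descriptors equals the class
#' vocabulary's expected chain count, and a *sum composition* when a single
#' descriptor stands for several unresolved chains (e.g. `"PG(30:0)"`).
#' Unknown class codes yield `lipid_class = "other"`, with the chain or sum
#' composition still parsed.
#'
#' @param name A single shorthand lipid name (non-empty character).
#' @param class_chains Named integer vector extending/overriding the built-in
#'   class vocabulary (see [lipid_class_vocabulary()]).
#' @return An object of class `lipid_species`: a list with fields
#'   `raw_name`, `lipid_class`, `class_raw`, `chains` (data frame with
#'   columns `carbons`, `double_bonds`, `ether_prefix`, `hydroxyl_prefix`,
#'   `isotope_label`), `species_label`, `sum_carbons`, `sum_double_bonds`
#'   and `chain_resolution` (`"chain_resolved"` or `"sum_composition"`).
#' @examples
#' parse_lipid_name("LPG(13:0)")
#' parse_lipid_name("PG(15:0_18:1-d7)")
#' parse_lipid_name("PG(30:0)")$chain_resolution
#' @export
parse_lipid_name <- function(name, class_chains = lipid_class_vocabulary()) {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !nzchar(trimws(name))) {
    .stopf("lipid name must be a single non-empty character string")
  }
  raw <- name
  name <- trimws(name)

  m <- regmatches(
    name, regexec("^([^()]+?)\\s*\\(([^()]*)\\)$", name)
  )[[1L]]
  if (length(m) == 0L) {
    # bare class name with no descriptor, e.g. "cholesterol"
    class_raw <- name
    body <- ""
  } else {
    class_raw <- m[2L]
    body <- m[3L]
  }

  class_key <- class_raw
  if (class_key %in% names(.CLASS_ALIASES)) {
    class_key <- .CLASS_ALIASES[[class_key]]
  }
  known <- class_key %in% names(class_chains)
  lipid_class <- if (known) class_key else "other"
  expected <- if (known) class_chains[[class_key]] else NA_integer_

  species_label <- NA_character_
  tokens <- character(0)
  if (nzchar(body)) {
    tokens <- trimws(strsplit(body, "[_/]")[[1L]])
    # a lone "dN" token is a species-level isotope label, e.g. cholesterol(d7)
    if (length(tokens) == 1L && grepl("^d[0-9]+$", tokens[1L])) {
      species_label <- tokens[1L]
      tokens <- character(0)
    }
  }

  chains_list <- lapply(tokens, .parse_chain_token, name = raw)
  chains <- if (length(chains_list)) {
    do.call(rbind, lapply(chains_list, function(ch) {
      data.frame(
        carbons = ch$carbons, double_bonds = ch$double_bonds,
        ether_prefix = ch$ether_prefix, hydroxyl_prefix = ch$hydroxyl_prefix,
        isotope_label = ch$isotope_label, stringsAsFactors = FALSE
      )
    }))
  } else {
    data.frame(
      carbons = integer(0), double_bonds = integer(0),
      ether_prefix = character(0), hydroxyl_prefix = character(0),
      isotope_label = character(0), stringsAsFactors = FALSE
    )
  }

  n_tok <- nrow(chains)
  if (!is.na(expected) && n_tok == expected) {
    resolution <- "chain_resolved"
  } else if (n_tok == 0L) {
    # no chain descriptors at all (e.g. cholesterol): nothing unresolved
    resolution <- "chain_resolved"
  } else if (n_tok == 1L) {
    # one descriptor for a class expecting several (or unknown) chains:
    # only the sum composition is known
    resolution <- "sum_composition"
  } else {
    resolution <- "chain_resolved"
  }

  structure(
    list(
      raw_name = raw,
      lipid_class = lipid_class,
      class_raw = class_raw,
      chains = if (resolution == "chain_resolved") chains else chains[0, ],
      species_label = species_label,
      sum_carbons = if (n_tok) sum(chains$carbons) else 0L,
      sum_double_bonds = if (n_tok) sum(chains$double_bonds) else 0L,
      chain_resolution = resolution,
      # for sum compositions keep any label carried by the descriptor
      sum_label = if (resolution == "sum_composition" &&
                        !is.na(chains$isotope_label[1L])) {
        chains$isotope_label[1L]
      } else {
        NA_character_
      },
      n_descriptors = n_tok
    ),
    class = "lipid_species"
  )
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(
    sprintf(
      "<lipid_species> %s  class=%s  sum=%d:%d  [%s]%s\n",
      x$raw_name, x$lipid_class, x$sum_carbons, x$sum_double_bonds,
      x$chain_resolution,
      if (is_internal_standard(x)) "  internal standard" else ""
    )
  )
  invisible(x)
}

#' Render a lipid species back to shorthand text
#'
#' Inverse of [parse_lipid_name()] for chain-resolved species: rendering and
#' re-parsing yields an identical species.  Sum-composition species render as
#' `CLASS(C:D)`.
#'
#' @param species A `lipid_species`.
#' @return Character shorthand name.
#' @export
render_lipid_name <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  cls <- if (species$lipid_class == "other") {
    species$class_raw
  } else {
    species$lipid_class
  }
  if (!is.na(species$species_label)) {
    return(paste0(cls, "(", species$species_label, ")"))
  }
  if (species$chain_resolution == "sum_composition") {
    lab <- if (is.na(species$sum_label)) "" else paste0("-", species$sum_label)
    return(paste0(
      cls, "(", species$sum_carbons, ":", species$sum_double_bonds, lab, ")"
    ))
  }
  if (nrow(species$chains) == 0L) {
    return(cls)
  }
  paste0(cls, "(", paste(.render_chain(species$chains), collapse = "_"), ")")
}

#' Acyl-chain parity of a lipid species
#'
#' A chain-resolved species is `"odd"` if at least one acyl chain has an odd
#' carbon count, otherwise `"even"`.  A sum-composition species with an odd
#' total carbon count must contain an odd chain and is `"odd"`; with an even
#' total and unresolved chains the parity of the individual chains cannot be
#' decided and the label is `"ambiguous"`.  For stratified counting,
#' ambiguous species are conventionally pooled with the even stratum (see
#' [parity_stratum()]): only provably-odd species enter the odd stratum,
#' matching the conservative reading of odd chains as near-universally
#' bacterial.
#'
#' @param species A `lipid_species` (or character name, parsed on the fly).
#' @return One of `"odd"`, `"even"`, `"ambiguous"`.
#' @examples
#' chain_parity("LPG(13:0)")
#' chain_parity("PG(15:0_15:0)")
#' chain_parity("PG(30:0)")
#' @export
chain_parity <- function(species) {
  if (is.character(species)) {
    species <- parse_lipid_name(species)
  }
  stopifnot(inherits(species, "lipid_species"))
  if (species$chain_resolution == "chain_resolved") {
    if (nrow(species$chains) == 0L) {
      return("even")
    }
    if (any(species$chains$carbons %% 2L == 1L)) "odd" else "even"
  } else {
    if (species$sum_carbons %% 2L == 1L) "odd" else "ambiguous"
  }
}

#' Collapse parity labels into the two counting strata
#'
#' @param parity Character vector of `"odd"`, `"even"`, `"ambiguous"`.
#' @return `"odd"` or `"even"` (ambiguous pooled with even).
#' @export
parity_stratum <- function(parity) {
  stopifnot(all(parity %in% c("odd", "even", "ambiguous")))
  ifelse(parity == "odd", "odd", "even")
}

#' Canonical identity key for a lipid species
#'
#' A stable text key used to match compounds across datasets: the class code
#' plus the chain descriptors sorted by (carbons, double bonds, label), so
#' that `PG(18:1_15:0)` and `PG(15:0_18:1)` share a key while isotope-labeled
#' standards stay distinct from their unlabeled analogues.  The key is
#' idempotent: parsing a key and re-keying returns the same text.
#'
#' @param species A `lipid_species` (or character name, parsed on the fly).
#' @return Character key.
#' @examples
#' canonical_key("PG(18:1_15:0)") == canonical_key("PG(15:0_18:1)")
#' @export
canonical_key <- function(species) {
  if (is.character(species)) {
    species <- parse_lipid_name(species)
  }
  stopifnot(inherits(species, "lipid_species"))
  cls <- if (species$lipid_class == "other") {
    species$class_raw
  } else {
    species$lipid_class
  }
  if (!is.na(species$species_label)) {
    return(paste0(cls, "(", species$species_label, ")"))
  }
  if (species$chain_resolution == "sum_composition") {
    lab <- if (is.na(species$sum_label)) "" else paste0("-", species$sum_label)
    return(paste0(
      cls, "(", species$sum_carbons, ":", species$sum_double_bonds, lab, ")"
    ))
  }
  if (nrow(species$chains) == 0L) {
    return(cls)
  }
  ch <- species$chains
  ord <- order(
    ch$carbons, ch$double_bonds,
    ifelse(is.na(ch$isotope_label), "", ch$isotope_label),
    ifelse(is.na(ch$ether_prefix), "", ch$ether_prefix),
    ifelse(is.na(ch$hydroxyl_prefix), "", ch$hydroxyl_prefix)
  )
  paste0(cls, "(", paste(.render_chain(ch[ord, ]), collapse = "_"), ")")
}

#' Is a species an isotope-labeled internal standard?
#'
#' True when any acyl chain, the sum descriptor, or the species itself
#' carries a deuterium label (e.g. the one-per-class deuterated spike-in
#' standards used for intensity normalization).
#'
#' @param species A `lipid_species` (or character name, parsed on the fly).
#' @return Logical.
#' @examples
#' is_internal_standard("SM(18:1-d7)")
#' is_internal_standard("LPG(13:0)")
#' @export
is_internal_standard <- function(species) {
  if (is.character(species)) {
    species <- parse_lipid_name(species)
  }
  stopifnot(inherits(species, "lipid_species"))
  !is.na(species$species_label) ||
    !is.na(species$sum_label) ||
    (nrow(species$chains) > 0L && any(!is.na(species$chains$isotope_label)))
}

#' Parse a batch of lipid names into an annotation table
#'
#' @param names Character vector of shorthand lipid names.
#' @param class_chains Class vocabulary, see [parse_lipid_name()].
#' @return Data frame with one row per name and columns `raw_name`, `class`,
#'   `chains` (rendered resolved chains or `""`), `sum_composition` (`"C:D"`),
#'   `parity`, `is_internal_standard`, `canonical_key`.
#' @export
parse_lipid_names <- function(names, class_chains = lipid_class_vocabulary()) {
  stopifnot(is.character(names))
  rows <- lapply(names, function(nm) {
    sp <- parse_lipid_name(nm, class_chains = class_chains)
    data.frame(
      raw_name = nm,
      class = sp$lipid_class,
      chains = if (nrow(sp$chains)) {
        paste(.render_chain(sp$chains), collapse = "_")
      } else {
        ""
      },
      sum_composition = paste0(sp$sum_carbons, ":", sp$sum_double_bonds),
      parity = chain_parity(sp),
      is_internal_standard = is_internal_standard(sp),
      canonical_key = canonical_key(sp),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Annotate a file of lipid names
#'
#' Batch interface: reads a one-column text file of shorthand names (no
#' header) and writes a TSV annotation table (see [parse_lipid_names()]).
#'
#' @param input Path to a one-column text file of lipid names.
#' @param output Path of the TSV to write.
#' @return The annotation data frame, invisibly.
#' @export
annotate_lipid_file <- function(input, output) {
  names <- readLines(input)
  names <- names[nzchar(trimws(names))]
  tab <- parse_lipid_names(names)
  utils::write.table(
    tab, output,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(tab)
}

#' Names of the deuterated one-per-class spike-in standards
#'
#' The standard mix spiked into every sample for per-class normalization:
#' one deuterated species per covered lipid class.
#'
#' @return Character vector of shorthand names.
#' @export
splash_standard_names <- function() {
  c(
    "PC(15:0_18:1-d7)", "PE(15:0_18:1-d7)", "PS(15:0_18:1-d7)",
    "PG(15:0_18:1-d7)", "PI(15:0_18:1-d7)", "PA(15:0_18:1-d7)",
    "LPC(18:1-d7)", "LPE(18:1-d7)", "cholesteryl ester(18:1-d7)",
    "MG(18:1-d7)", "DG(15:0_18:1-d7)", "TG(15:0_18:1-d7_15:0)",
    "SM(18:1-d7)", "cholesterol(d7)"
  )
}
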