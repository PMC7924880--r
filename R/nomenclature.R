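#' Lipid classes covered by the quantitative panel
#'
#' The 13 lipid classes of the targeted internal-standard kit. The code set is
#' closed: any species name must resolve to one of these codes.
#'
#' @return A data frame with columns `code` and `label`.
#' @export
#' @examples
#' lipid_classes()
lipid_classes <- function() {
  data.frame(
    code = c("Cer", "CE", "DG", "ACer", "FA", "HexCer", "LacCer",
             "LPC", "LPE", "PC", "PE", "SM", "TG"),
    label = c("ceramide", "cholesteryl ester", "diacylglycerol",
              "acylceramide", "fatty acid", "hexosylceramide",
              "lactosylceramide", "lysophosphatidylcholine",
              "lysophosphatidylethanolamine", "phosphatidylcholine",
              "phosphatidylethanolamine", "sphingomyelin", "triacylglycerol"),
    stringsAsFactors = FALSE
  )
}

# class token spellings accepted in input, mapped to canonical codes;
# hyphenated spellings co-occur with fused ones in the wild and are kept verbatim
.class_aliases <- c(
  "Cer" = "Cer", "CE" = "CE", "DG" = "DG", "ACer" = "ACer", "FA" = "FA",
  "HexCer" = "HexCer", "Hex-Cer" = "HexCer",
  "LacCer" = "LacCer", "Lac-Cer" = "LacCer",
  "LPC" = "LPC", "LPE" = "LPE", "PC" = "PC", "PE" = "PE",
  "SM" = "SM", "TG" = "TG"
)

# expected number of explicit chain tokens per class; TG carries one explicit
# chain plus a two-chain residual, lyso/CE/FA species carry a single chain
.chain_counts <- list(
  Cer = 2L, CE = 1L, DG = 2L, ACer = c(2L, 3L), FA = 1L,
  HexCer = 2L, LacCer = 2L, LPC = 1L, LPE = 1L, PC = 2L, PE = 2L,
  SM = 2L, TG = 2L
)

.parse_chain <- function(token, name, pos) {
  ether <- "none"
  body <- token
  if (grepl("^P-", body)) { ether <- "P"; body <- sub("^P-", "", body) }
  else if (grepl("^O-", body)) { ether <- "O"; body <- sub("^O-", "", body) }
  m <- regmatches(body, regexec("^([0-9]+):([0-9]+)(;O([0-9]?))?$", body))[[1]]
  if (length(m) == 0) {
    stop(sprintf("unparseable chain token '%s' at position %d in '%s'",
                 token, pos, name), call. = FALSE)
  }
  carbons <- as.integer(m[2])
  dbs <- as.integer(m[3])
  ox <- 0L
  if (nzchar(m[4])) ox <- if (nzchar(m[5])) as.integer(m[5]) else 1L
  if (carbons < dbs) {
    stop(sprintf("chain '%s' in '%s' has more double bonds than carbons",
                 token, name), call. = FALSE)
  }
  if (ox > 3L) {
    stop(sprintf("chain '%s' in '%s' has unsupported oxygen count %d",
                 token, name, ox), call. = FALSE)
  }
  list(carbons = carbons, double_bonds = dbs, oxygens = ox,
       ether_prefix = ether, token = token)
}

.format_chain <- function(chain) chain$token

#' Parse a lipid shorthand name
#'
#' Parses Lipidyzer / LIPID-MAPS-style shorthand (`"TG 20:4_33:1"`,
#' `"PE P-16:0/20:3"`, `"Hex-Cer 18:1;O2/22:0"`, ...) into its lipid class and
#' chain descriptors. Triacylglycerol names carry one explicit fatty-acid chain
#' and a residual summarizing the remaining two chains; the `"/"` separator
#' marks known sn-linkage, `"_"` unknown. Hyphenated class spellings
#' (`"Hex-Cer"`, `"Lac-Cer"`) are accepted as aliases and preserved verbatim on
#' serialization.
#'
#' @param name A single lipid shorthand name.
#' @return An object of class `lipid_species` with fields `raw_name`,
#'   `lipid_class`, `class_token`, `chains` (list of chain descriptors with
#'   `carbons`, `double_bonds`, `oxygens`, `ether_prefix`), `residual` (TG
#'   only), `separator`, `linkage_known`, `total_carbons`, `total_double_bonds`.
#' @export
#' @examples
#' sp <- parse_lipid_name("TG 20:4_33:1")
#' sp$total_carbons       # 53
#' sp$total_double_bonds  # 5
#' parse_lipid_name("PE P-16:0/20:3")$chains[[1]]$ether_prefix
parse_lipid_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name))) {
    stop("'name' must be a single non-empty string", call. = FALSE)
  }
  raw <- name
  nm <- gsub("[[:space:]]+", " ", trimws(name))
  sp <- regexpr(" ", nm, fixed = TRUE)
  if (sp < 0) {
    stop(sprintf("no chain block found in '%s' (position %d)", raw, nchar(nm)),
         call. = FALSE)
  }
  class_token <- substr(nm, 1L, sp - 1L)
  rest <- substr(nm, sp + 1L, nchar(nm))
  if (!class_token %in% names(.class_aliases)) {
    stop(sprintf("unknown lipid class code '%s' at position 1 in '%s'",
                 class_token, raw), call. = FALSE)
  }
  code <- unname(.class_aliases[class_token])

  sep <- if (grepl("/", rest, fixed = TRUE)) "/" else "_"
  tokens <- strsplit(rest, "[_/]")[[1]]
  if (any(!nzchar(tokens))) {
    stop(sprintf("empty chain token in '%s'", raw), call. = FALSE)
  }
  chains <- lapply(seq_along(tokens),
                   function(i) .parse_chain(tokens[i], raw, i))

  expected <- .chain_counts[[code]]
  if (!length(tokens) %in% expected) {
    stop(sprintf("class %s expects %s chain token(s), got %d in '%s'",
                 code, paste(expected, collapse = " or "), length(tokens), raw),
         call. = FALSE)
  }

  residual <- NULL
  if (code == "TG") {
    residual <- chains[[2L]]
    chains <- chains[1L]
  }

  all_ch <- c(chains, if (!is.null(residual)) list(residual))
  structure(list(
    raw_name = raw,
    lipid_class = code,
    class_token = class_token,
    chains = chains,
    residual = residual,
    separator = if (length(tokens) > 1L) sep else NA_character_,
    linkage_known = if (length(tokens) > 1L) sep == "/" else NA,
    total_carbons = sum(vapply(all_ch, `[[`, integer(1), "carbons")),
    total_double_bonds = sum(vapply(all_ch, `[[`, integer(1), "double_bonds"))
  ), class = "lipid_species")
}

#' Serialize a parsed lipid species back to shorthand
#'
#' Inverse of [parse_lipid_name()]: reproduces the canonical form of the name
#' (single space between class token and chain block, original chain separator
#' and class spelling preserved).
#'
#' @param species A `lipid_species` object.
#' @return A character scalar.
#' @export
serialize_lipid_name <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  tokens <- vapply(species$chains, .format_chain, character(1))
  if (!is.null(species$residual)) {
    tokens <- c(tokens, .format_chain(species$residual))
  }
  block <- if (length(tokens) > 1L) {
    paste(tokens, collapse = species$separator)
  } else tokens
  paste(species$class_token, block)
}

#' @export
format.lipid_species <- function(x, ...) serialize_lipid_name(x)

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid_species> %s  [class %s, %d C, %d double bond(s)]\n",
              serialize_lipid_name(x), x$lipid_class,
              x$total_carbons, x$total_double_bonds))
  invisible(x)
}

#' Lipid class of a parsed species
#'
#' @param species A `lipid_species` object, or a character name which is parsed
#'   first.
#' @return The class code (one of the 13 codes in [lipid_classes()]).
#' @export
#' @examples
#' class_of("LPC 18:2")
class_of <- function(species) {
  if (is.character(species)) species <- parse_lipid_name(species)
  stopifnot(inherits(species, "lipid_species"))
  species$lipid_class
}

#' Validate a vector of lipid species column names
#'
#' Checks every name in a concentration-table header, collecting parse errors
#' instead of stopping at the first one.
#'
#' @param names Character vector of candidate species names.
#' @return A data frame with columns `name`, `ok` (logical), `lipid_class`
#'   (NA where unparseable) and `error` (message, NA where ok).
#' @export
validate_species_names <- function(names) {
  stopifnot(is.character(names))
  res <- lapply(names, function(nm) {
    out <- tryCatch(parse_lipid_name(nm), error = function(e) e)
    if (inherits(out, "error")) {
      list(ok = FALSE, cls = NA_character_, err = conditionMessage(out))
    } else {
      list(ok = TRUE, cls = out$lipid_class, err = NA_character_)
    }
  })
  data.frame(
    name = names,
    ok = vapply(res, `[[`, logical(1), "ok"),
    lipid_class = vapply(res, `[[`, character(1), "cls"),
    error = vapply(res, `[[`, character(1), "err"),
    stringsAsFactors = FALSE
  )
}
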