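#' @include AllClasses.R
NULL

.emptyEffectors <- function()
  data.frame(id = character(0), role = character(0),
             stringsAsFactors = FALSE)

.idPattern <- "[A-Za-z_][A-Za-z0-9_.-]*"

## "2 A + B" -> data.frame(id, coef); empty string -> empty side
.parseSide <- function(txt, lineNo) {
  txt <- trimws(txt)
  if (txt == "")
    return(data.frame(id = character(0), coef = numeric(0),
                      stringsAsFactors = FALSE))
  terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  rx <- sprintf("^(([0-9]*\\.?[0-9]+(/[0-9]+)?)[ \t]+)?(%s)$", .idPattern)
  m <- regmatches(terms, regexec(rx, terms))
  if (any(vapply(m, length, integer(1)) == 0L))
    stop(sprintf("line %d: cannot parse species term '%s'", lineNo,
                 terms[which(vapply(m, length, integer(1)) == 0L)[1]]))
  coef <- vapply(m, function(g) {
    if (g[3] == "") return(1)
    if (grepl("/", g[3], fixed = TRUE)) {
      parts <- as.numeric(strsplit(g[3], "/", fixed = TRUE)[[1]])
      return(parts[1] / parts[2])
    }
    as.numeric(g[3])
  }, numeric(1))
  if (any(coef <= 0))
    stop(sprintf("line %d: stoichiometric coefficients must be positive",
                 lineNo))
  data.frame(id = vapply(m, `[`, character(1), 5), coef = coef,
             stringsAsFactors = FALSE)
}

.parseEffectors <- function(txt, lineNo) {
  if (is.na(txt) || trimws(txt) == "") return(.emptyEffectors())
  clauses <- trimws(strsplit(txt, ";", fixed = TRUE)[[1]])
  out <- lapply(clauses, function(cl) {
    parts <- strsplit(cl, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("line %d: malformed effector clause '%s'", lineNo, cl))
    role <- trimws(parts[1])
    if (!role %in% c("inhibitor", "activator"))
      stop(sprintf("line %d: unknown effector role '%s'", lineNo, role))
    ids <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    if (!all(grepl(sprintf("^%s$", .idPattern), ids)))
      stop(sprintf("line %d: malformed effector id in '%s'", lineNo, cl))
    data.frame(id = ids, role = role, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Parse a plain-text reaction list into a ReactionNetwork
#'
#' One reaction per line, e.g. `"2 A + B -> C"` (irreversible) or
#' `"A <-> B"` (reversible), with an optional reaction-name prefix
#' (`"r1: A -> B"`) and an optional effector suffix
#' `"| inhibitor: X; activator: Y, Z"`. Stoichiometric coefficients are
#' positive numbers (`2 A`, `0.5 A` or `1/2 A`); omitted coefficients are
#' 1. Blank lines and `#` comments are ignored. Metabolites are collected
#' in first-appearance order.
#'
#' @param source character vector of lines, a single string with embedded
#'   newlines, or a file path (when `isPath = TRUE` or when a single-line
#'   string names an existing file).
#' @param isPath force interpretation of `source` as a file path.
#' @return A \linkS4class{ReactionNetwork}.
#' @examples
#' net <- parseReactions("A -> B\nB -> C\nC -> D")
#' metabolites(net)
#' @seealso [stoichiometricMatrix()], [interactionMatrix()], [readSBML()]
#' @export
parseReactions <- function(source, isPath = FALSE) {
  if (isPath || (length(source) == 1L && !grepl("\n", source) &&
                 !grepl("->", source, fixed = TRUE) &&
                 file.exists(source)))
    source <- readLines(source)
  lines <- unlist(strsplit(source, "\n", fixed = TRUE))
  mets <- character(0)
  rxns <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    if (trimws(line) == "") next
    parts <- strsplit(line, "|", fixed = TRUE)[[1]]
    eff <- .parseEffectors(if (length(parts) > 1L)
      paste(parts[-1], collapse = ";") else NA_character_, i)
    body <- parts[1]
    name <- sprintf("r%d", length(rxns) + 1L)
    nm <- regmatches(body, regexec(
      sprintf("^[ \t]*(%s)[ \t]*:(.*)$", .idPattern), body))[[1]]
    if (length(nm)) { name <- nm[2]; body <- nm[3] }
    reversible <- grepl("<->", body, fixed = TRUE)
    arrow <- if (reversible) "<->" else "->"
    sides <- strsplit(body, arrow, fixed = TRUE)[[1]]
    if (!grepl(arrow, body, fixed = TRUE) || length(sides) > 2L)
      stop(sprintf("line %d: expected exactly one '%s' arrow", i, arrow))
    if (length(sides) == 1L) sides <- c(sides, "")
    subs <- .parseSide(sides[1], i)
    prods <- .parseSide(sides[2], i)
    mets <- union(mets, c(subs$id, prods$id, eff$id))
    rxns[[length(rxns) + 1L]] <-
      list(name = name, substrates = subs, products = prods,
           reversible = reversible, effectors = eff)
  }
  new("ReactionNetwork", metabolites = mets, reactions = rxns)
}

#' Import a reaction network from an SBML file
#'
#' Reads the minimal SBML subset needed here: `species` become
#' metabolites, `reaction` elements (with `listOfReactants`,
#' `listOfProducts` and their `stoichiometry` attributes, default 1)
#' become reactions, and `listOfModifiers` species become effectors with
#' role `"modifier"` (treated like annotated effectors when building the
#' interaction matrix). The `reversible` attribute is honoured.
#' Compartments, kinetic laws and units are ignored.
#'
#' @param path SBML file path.
#' @return A \linkS4class{ReactionNetwork}.
#' @export
readSBML <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  speciesNodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- xml2::xml_attr(speciesNodes, "id")
  refs <- function(rxn, tag) {
    nodes <- xml2::xml_find_all(
      rxn, sprintf("./%s/speciesReference", tag))
    coef <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
    coef[is.na(coef)] <- 1
    data.frame(id = xml2::xml_attr(nodes, "species"), coef = coef,
               stringsAsFactors = FALSE)
  }
  rxnNodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- lapply(seq_along(rxnNodes), function(i) {
    rxn <- rxnNodes[[i]]
    mods <- xml2::xml_find_all(rxn,
      "./listOfModifiers/modifierSpeciesReference")
    eff <- if (length(mods))
      data.frame(id = xml2::xml_attr(mods, "species"), role = "modifier",
                 stringsAsFactors = FALSE)
      else .emptyEffectors()
    rev <- identical(xml2::xml_attr(rxn, "reversible"), "true")
    nm <- xml2::xml_attr(rxn, "id")
    list(name = if (is.na(nm)) sprintf("r%d", i) else nm,
         substrates = refs(rxn, "listOfReactants"),
         products = refs(rxn, "listOfProducts"),
         reversible = rev, effectors = eff)
  })
  used <- unique(unlist(lapply(rxns, function(r)
    c(r$substrates$id, r$products$id, r$effectors$id))))
  new("ReactionNetwork", metabolites = union(mets, used),
      reactions = rxns)
}

#' Stoichiometric matrix N of a reaction network
#'
#' Entry (i, r) is the net stoichiometric coefficient of metabolite i in
#' reaction r: product coefficient minus substrate coefficient. A
#' metabolite appearing on both sides with equal coefficients nets to 0.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @return `n x k` numeric matrix with metabolite row names and reaction
#'   column names.
#' @export
stoichiometricMatrix <- function(network) {
  stopifnot(is(network, "ReactionNetwork"))
  mets <- network@metabolites
  k <- length(network@reactions)
  N <- matrix(0, length(mets), k,
              dimnames = list(mets,
                              vapply(network@reactions, `[[`,
                                     character(1), "name")))
  for (r in seq_len(k)) {
    rx <- network@reactions[[r]]
    for (i in seq_len(nrow(rx$substrates)))
      N[rx$substrates$id[i], r] <- N[rx$substrates$id[i], r] -
        rx$substrates$coef[i]
    for (i in seq_len(nrow(rx$products)))
      N[rx$products$id[i], r] <- N[rx$products$id[i], r] +
        rx$products$coef[i]
  }
  N
}

#' Binary metabolic interaction matrix Y
#'
#' Builds the `n x n` 0/1 matrix connecting metabolic functions (rows) to
#' the metabolite concentrations they biochemically depend on (columns):
#' entry (i, j) is 1 iff metabolite j is a substrate — or an annotated
#' effector (inhibitor, activator, modifier) — of at least one reaction
#' whose net stoichiometric entry for metabolite i is nonzero. Under the
#' default `"both_directions"` policy the products of a reversible
#' reaction also count as substrates (of its reverse direction); under
#' `"forward_only"` they do not.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param reversiblePolicy `"both_directions"` or `"forward_only"`.
#' @return An \linkS4class{InteractionMatrix}.
#' @examples
#' Y <- interactionMatrix(parseReactions("A -> B\nB -> C\nC -> D"))
#' interactionEntries(Y)["B", "A"]   # f(B) depends on [A]: 1
#' @export
interactionMatrix <- function(network,
                              reversiblePolicy = c("both_directions",
                                                   "forward_only")) {
  stopifnot(is(network, "ReactionNetwork"))
  reversiblePolicy <- match.arg(reversiblePolicy)
  mets <- network@metabolites
  n <- length(mets)
  Y <- matrix(0L, n, n, dimnames = list(mets, mets))
  N <- stoichiometricMatrix(network)
  for (r in seq_along(network@reactions)) {
    rx <- network@reactions[[r]]
    drivers <- c(rx$substrates$id, rx$effectors$id)
    if (rx$reversible && reversiblePolicy == "both_directions")
      drivers <- c(drivers, rx$products$id)
    affected <- mets[N[, r] != 0]
    if (length(affected) && length(drivers))
      Y[affected, unique(drivers)] <- 1L
  }
  new("InteractionMatrix", entries = Y)
}

#' Write / read a labeled 0/1 interaction matrix as TSV
#'
#' @param Y an \linkS4class{InteractionMatrix}.
#' @param path file path.
#' @return `writeInteractionMatrix` returns `path` invisibly;
#'   `readInteractionMatrix` returns an \linkS4class{InteractionMatrix}.
#' @export
writeInteractionMatrix <- function(Y, path) {
  stopifnot(is(Y, "InteractionMatrix"))
  df <- data.frame(metabolite = rownames(Y@entries), Y@entries,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeInteractionMatrix
#' @export
readInteractionMatrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$metabolite
  new("InteractionMatrix", entries = m)
}
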