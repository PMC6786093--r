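#' Parse a MeSH-style disease hierarchy
#'
#' Accepts either the ASCII descriptor dialect (records carrying `MH = name`
#' followed by one or more `MN = treenumber` lines) or a simplified
#' two-column `name<TAB>treenumber` TSV; the dialect is auto-detected. A term
#' listed several times accumulates the union of its tree numbers. Terms with
#' no tree number are skipped with a warning.
#'
#' Tree numbers are dot-delimited codes (`C14.280.647.500`); truncating at
#' the last dot yields the parent, so the ancestor closure of a term is the
#' set of its prefixes.
#'
#' @param path Path to the descriptor or TSV file.
#' @return An object of class `disease_ontology`: named list `terms`
#'   (normalised term name -> character vector of tree numbers) plus the
#'   original display names.
#' @export
parse_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^MH = ", lines))) {
    terms <- list()
    current <- NULL
    for (ln in lines) {
      if (startsWith(ln, "MH = ")) {
        current <- trimws(substring(ln, 6))
        if (is.null(terms[[current]])) terms[[current]] <- character()
      } else if (startsWith(ln, "MN = ") && !is.null(current)) {
        terms[[current]] <- c(terms[[current]], trimws(substring(ln, 6)))
      } else if (startsWith(ln, "*NEWRECORD")) {
        current <- NULL
      }
    }
    names_disp <- names(terms)
    treenums <- terms
  } else {
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(parts) < 2
    if (all(bad)) stop_format("%s is neither MeSH ASCII nor name<TAB>treenum TSV", path)
    parts <- parts[!bad]
    nm <- trimws(vapply(parts, `[`, character(1), 1))
    tn <- trimws(vapply(parts, `[`, character(1), 2))
    # drop a header row if present (second field not tree-number shaped)
    if (length(nm) && !grepl("^[A-Za-z][0-9]", tn[1])) {
      nm <- nm[-1]; tn <- tn[-1]
    }
    names_disp <- unique(nm)
    treenums <- lapply(names_disp, function(d) unique(tn[nm == d]))
    names(treenums) <- names_disp
  }
  empty <- lengths(treenums) == 0
  if (any(empty)) {
    warning("skipping ", sum(empty), " term(s) with no tree numbers: ",
            paste(utils::head(names_disp[empty], 5), collapse = ", "))
    treenums <- treenums[!empty]
    names_disp <- names_disp[!empty]
  }
  new_disease_ontology(treenums, names_disp)
}

new_disease_ontology <- function(treenums, display = names(treenums)) {
  treenums <- lapply(treenums, unique)
  keys <- normalize_disease_name(display)
  terms <- treenums
  names(terms) <- keys
  structure(list(terms = terms, display = display), class = "disease_ontology")
}

#' @export
print.disease_ontology <- function(x, ...) {
  cat(sprintf("disease_ontology: %d terms, %d tree numbers\n",
              length(x$terms), length(unlist(x$terms))))
  invisible(x)
}

#' Resolve a disease name against the ontology
#'
#' Matching is exact but case-insensitive after whitespace/comma
#' normalisation.
#'
#' @param ontology A `disease_ontology`.
#' @param disease Disease name.
#' @return Character vector of tree numbers, or `NULL` when unresolvable.
#' @export
resolve_disease <- function(ontology, disease) {
  ontology$terms[[normalize_disease_name(disease)]]
}

# All prefixes of a tree number, self included, ordered self -> root.
treenum_ancestors <- function(tn) {
  parts <- strsplit(tn, ".", fixed = TRUE)[[1]]
  vapply(rev(seq_along(parts)),
         function(k) paste(parts[seq_len(k)], collapse = "."),
         character(1))
}
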