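#' @title Linking metabolites to metabolic pathways
#' @name pathway_linking
#' @description
#' Joins metabolite compound identifiers (e.g. InChIKeys) to pathway
#' compound lists and computes the fraction of significant
#' pathway-metabolite associations that link a metabolite to a pathway it
#' belongs to (producing or consuming it). Keys are opaque strings after
#' uppercasing and trimming; no chemistry-aware matching.
NULL

normalize_key <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Map metabolites to the pathways containing their compound
#'
#' Inner-join semantics on the normalized compound key: metabolites with
#' no key or no match map to the empty set. Duplicate map rows are
#' collapsed.
#'
#' @param annotations data.frame with `metabolite_id` and `compound_key`.
#' @param cmap data.frame with `compound_key` and `pathway_id`.
#' @return named list: metabolite_id -> character vector of pathway ids.
#' @export
link_metabolites <- function(annotations, cmap) {
  cmap$compound_key <- normalize_key(cmap$compound_key)
  cmap <- unique(cmap[, c("compound_key", "pathway_id")])
  by_key <- split(cmap$pathway_id, cmap$compound_key)
  keys <- normalize_key(annotations$compound_key)
  out <- lapply(keys, function(k) {
    if (is.na(k) || k == "" || k == "NA") return(character(0))
    v <- by_key[[k]]
    if (is.null(v)) character(0) else sort(unique(v))
  })
  names(out) <- annotations$metabolite_id
  out
}

#' Fraction of associations linked to a producing/consuming pathway
#'
#' Over the unique significant (metabolite, pathway-feature) pairs, an
#' association counts as linked iff the metabolite's pathway set contains
#' the associated pathway.
#'
#' @param assoc association data.frame with pathway features
#'   (feature_id = pathway id), already filtered or carrying a `q` column.
#' @param links metabolite -> pathway set from [link_metabolites()].
#' @param fdr significance threshold applied if a `q` column is present.
#' @return list with `n_linked`, `n_total`, `fraction`,
#'   `n_linked_metabolites`.
#' @export
functional_link_fraction <- function(assoc, links, fdr = 0.05) {
  if (!is.null(assoc$q)) assoc <- assoc[assoc$q <= fdr, , drop = FALSE]
  pairs <- unique(assoc[, c("metabolite_id", "feature_id")])
  if (nrow(pairs) == 0) stop("functional_link_fraction: no significant associations")
  linked <- vapply(seq_len(nrow(pairs)), function(i) {
    pairs$feature_id[i] %in% links[[pairs$metabolite_id[i]]]
  }, logical(1))
  list(n_linked = sum(linked), n_total = nrow(pairs),
       fraction = sum(linked) / nrow(pairs),
       n_linked_metabolites = length(unique(pairs$metabolite_id[linked])))
}
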