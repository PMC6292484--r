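#' Read a tip-trait table
#'
#' Reads a tab-separated table with header `taxon<TAB>value` mapping tip
#' labels to a single continuous trait (e.g. log body mass in log-g, or mean
#' latitude in degrees).
#'
#' @param file path to the TSV file.
#' @return a named numeric vector of trait values.
#' @export
readTraitTable <- function(file) {
  d <- utils::read.delim(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("taxon", "value") %in% names(d)))
    stop("trait table must have columns 'taxon' and 'value'")
  v <- as.numeric(d$value)
  if (anyNA(v) || any(!is.finite(v))) stop("trait values must be finite numbers")
  if (anyDuplicated(d$taxon)) stop("duplicate taxa in trait table")
  stats::setNames(v, d$taxon)
}

#' @rdname readTraitTable
#' @param traits named numeric vector of trait values.
#' @export
writeTraitTable <- function(traits, file) {
  utils::write.table(
    data.frame(taxon = names(traits), value = unname(traits)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Bind trait observations to a tree
#'
#' Produces a state-vector template: one value slot per node, with tip values
#' fixed to the observations and internal states marked unobserved (to be
#' sampled). Labelled degree-2 (sampled ancestor) internal nodes whose label
#' appears in the table are also bound as observed.
#'
#' @param tree a `timeTree`.
#' @param traits named numeric vector (names = tip labels).
#' @return a list with `values` (numeric per node, `NA` where unobserved) and
#'   `observed` (logical per node).
#' @export
bindTraits <- function(tree, traits) {
  stopifnot(inherits(tree, "timeTree"))
  labs <- tree$phy$tip.label
  miss <- setdiff(labs, names(traits))
  if (length(miss))
    stop("no trait value for tip(s): ", paste(miss, collapse = ", "))
  known <- labs
  m <- nNodesTotal(tree)
  values <- rep(NA_real_, m)
  observed <- rep(FALSE, m)
  values[seq_len(tree$N)] <- traits[labs]
  observed[seq_len(tree$N)] <- TRUE
  # sampled-ancestor nodes: labelled internal nodes with a matching entry
  if (!is.null(tree$phy$node.label)) {
    nl <- tree$phy$node.label
    for (k in seq_along(nl)) {
      if (nzchar(nl[k]) && nl[k] %in% names(traits)) {
        idx <- tree$N + k
        values[idx] <- traits[[nl[k]]]
        observed[idx] <- TRUE
        known <- c(known, nl[k])
      }
    }
  }
  extra <- setdiff(names(traits), known)
  if (length(extra))
    warning("ignoring trait entries with no matching tip: ",
            paste(extra, collapse = ", "))
  list(values = values, observed = observed)
}
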