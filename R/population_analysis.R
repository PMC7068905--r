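#' Bin accessions into latitude groups or labelled groups
#'
#' Latitude mode uses closed-left/open-right bins of `bin_width` degrees over
#' [-90, 90); accessions without a latitude fall into an "unassigned" group
#' that is reported but not binned. Label mode groups by the `group_label`
#' column.
#'
#' @param metadata data.frame with `accession_id` and either `latitude`
#'   (decimal degrees) or `group_label`.
#' @param mode "latitude" or "label".
#' @param bin_width latitude bin width in degrees (default 15).
#' @return named list of accession-id character vectors; names are group ids
#'   such as "[30,45)".
#' @export
make_groups <- function(metadata, mode = c("latitude", "label"),
                        bin_width = 15) {
  mode <- match.arg(mode)
  if (mode == "label") {
    return(split(as.character(metadata$accession_id),
                 as.character(metadata$group_label)))
  }
  lat <- as.numeric(metadata$latitude)
  lo <- bin_width * floor(lat / bin_width)
  grp <- ifelse(is.na(lat), "unassigned",
                sprintf("[%g,%g)", lo, lo + bin_width))
  split(as.character(metadata$accession_id), grp)
}

#' Stratified occurrence frequencies of uORF forms at each locus
#'
#' For every locus (reference anchor) of a gene, each analyzed accession
#' carries exactly one identifier or is "absent"; the frequency of each row
#' is its count over the group size, so every column sums to 1. Accessions
#' dropped by the mORF-start screen are excluded from all denominators and
#' returned separately.
#'
#' @param forms identifier-carrying forms from [assign_identifiers()].
#' @param accessions character vector of analyzed accession ids (post
#'   screen).
#' @param groups named list from [make_groups()]; may be `NULL` for a
#'   total-population-only table.
#' @param dropped accession ids removed by the mORF-start screen.
#' @return list with `table` (data.frame: anchor, identifier, then one
#'   frequency column `total` plus one per group) and `dropped`.
#' @export
compute_frequencies <- function(forms, accessions, groups = NULL,
                                dropped = character()) {
  accessions <- setdiff(accessions, dropped)
  if (!length(accessions)) stop("no analyzable accessions")
  if (!is.null(groups)) {
    groups <- lapply(groups, intersect, accessions)
    if (any(!lengths(groups))) stop("empty accession group")
  }
  anchors <- sort(unique(forms$anchor))
  rows <- list()
  for (a in anchors) {
    f <- forms[forms$anchor == a, , drop = FALSE]
    assign <- stats::setNames(rep("absent", length(accessions)), accessions)
    for (i in seq_len(nrow(f))) {
      carr <- strsplit(f$accessions[i], ",", fixed = TRUE)[[1L]]
      carr <- intersect(carr, accessions)
      assign[carr] <- f$identifier[i]
    }
    ids <- c(sort(unique(f$identifier)),
             if (any(assign == "absent")) "absent")
    for (id in ids) {
      row <- data.frame(anchor = a, identifier = id,
                        total = mean(assign == id),
                        stringsAsFactors = FALSE)
      if (!is.null(groups)) for (g in names(groups))
        row[[g]] <- mean(assign[groups[[g]]] == id)
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(anchor = integer(), identifier = character(),
               total = numeric())
  list(table = tab, dropped = dropped)
}

TRANSITION_CLASSES <- c("Type1-only<->Type2", "uORF-free<->Type1-only",
                        "uORF-free<->Type2")

transition_class <- function(a, b) {
  if (a == b) return(NA_character_)
  key <- paste(sort(c(a, b)), collapse = "|")
  switch(key,
         "Type1-only|Type2" = "Type1-only<->Type2",
         "Type1-only|uORF-free" = "uORF-free<->Type1-only",
         "Type2|uORF-free" = "uORF-free<->Type2",
         NA_character_)
}

#' Type-attribute transitions among the splicing models of a gene
#'
#' Compares the three-way uORF type attribute (uORF-free / Type1-only /
#' Type2) pairwise across a gene's splicing models on the reference, and
#' emits one call per distinct unordered attribute pair observed, restricted
#' to the three headline transition classes.
#'
#' @param attributes named character vector: model id -> attribute class.
#' @param gene_id gene id recorded on the calls.
#' @return data.frame: gene_id, context, from_attr, to_attr, class.
#' @export
splicing_model_transitions <- function(attributes, gene_id = NA_character_) {
  out <- list()
  uv <- sort(unique(unname(attributes)))
  pairs <- if (length(uv) >= 2L) utils::combn(uv, 2L, simplify = FALSE)
           else list()
  for (p in pairs) {
    cls <- transition_class(p[1L], p[2L])
    if (is.na(cls)) next
    out[[length(out) + 1L]] <- data.frame(
      gene_id = gene_id, context = "splicing-models",
      from_attr = p[1L], to_attr = p[2L], class = cls,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(gene_id = character(),
                                      context = character(),
                                      from_attr = character(),
                                      to_attr = character(),
                                      class = character()))
  do.call(rbind, out)
}

#' Population-level type-attribute transitions for one gene model
#'
#' Compares each accession's attribute (computed on its pseudo-cDNA) with the
#' reference attribute and tallies accessions per headline transition class.
#'
#' @param ref_attr reference attribute class.
#' @param acc_attrs named character vector: accession -> attribute class.
#' @param gene_id gene id recorded on the calls.
#' @return list with `calls` (data.frame: gene_id, context, from_attr,
#'   to_attr, class, n_accessions) and `per_accession` (data.frame:
#'   accession, class).
#' @export
population_transitions <- function(ref_attr, acc_attrs,
                                   gene_id = NA_character_) {
  cls <- vapply(acc_attrs, function(a) {
    x <- transition_class(ref_attr, a)
    if (is.na(x)) NA_character_ else x
  }, "")
  per <- data.frame(accession = names(acc_attrs), class = unname(cls),
                    stringsAsFactors = FALSE)
  per <- per[!is.na(per$class), , drop = FALSE]
  calls <- if (nrow(per)) {
    tab <- table(per$class)
    data.frame(gene_id = gene_id, context = "accessions",
               from_attr = ref_attr,
               to_attr = vapply(names(tab), function(k) {
                 ends <- strsplit(k, "<->", fixed = TRUE)[[1L]]
                 if (ends[1L] == ref_attr) ends[2L] else ends[1L]
               }, ""),
               class = names(tab), n_accessions = as.integer(tab),
               row.names = NULL, stringsAsFactors = FALSE)
  } else data.frame(gene_id = character(), context = character(),
                    from_attr = character(), to_attr = character(),
                    class = character(), n_accessions = integer())
  list(calls = calls, per_accession = per)
}

#' Fraction of uORF variant forms caused by two or more variants
#'
#' Over the distinct non-reference uORF forms of a cohort, the fraction whose
#' causal-variant count (SNPs plus INDELs) is at least two. Undefined (NA)
#' when the cohort has no non-reference form.
#'
#' @param forms identifier-carrying forms (possibly pooled over genes).
#' @return list with `fraction` (numeric or NA), `n_forms`, `n_multi`.
#' @export
multi_variant_fraction <- function(forms) {
  f <- forms[!forms$is_reference &
               forms$origin_class != "reference-identical", , drop = FALSE]
  if (!nrow(f)) return(list(fraction = NA_real_, n_forms = 0L, n_multi = 0L))
  multi <- (f$n_snps + f$n_indels) >= 2L
  list(fraction = mean(multi), n_forms = nrow(f), n_multi = sum(multi))
}
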