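#' Scan reference transcripts for uORFs
#'
#' Runs the uORF finder over every (or every representative) splicing model
#' of an annotation and attaches the per-model three-way type attribute.
#'
#' @param genome named contig vector from [read_genome()].
#' @param models named list of `transcript_model` (e.g. from
#'   [load_annotation()] or [select_representative()]).
#' @param start_codons start-codon set, default `"ATG"`.
#' @return list with `uorfs` (one data.frame over all models, columns as in
#'   [find_uorfs()]) and `attributes` (data.frame: gene_id, transcript_id,
#'   attribute, has_type3, n_uorfs).
#' @export
scan_uorfs <- function(genome, models, start_codons = "ATG") {
  tabs <- list(); attrs <- list()
  for (tm in models) {
    if (tm$leader_len == 0L) next               # no annotated leader
    sp <- spliced_cdna(tm, genome, start_codons)
    u <- find_uorfs(sp, start_codons)
    ga <- gene_type_attribute(u)
    tabs[[length(tabs) + 1L]] <- u
    attrs[[length(attrs) + 1L]] <- data.frame(
      gene_id = tm$gene_id, transcript_id = tm$transcript_id,
      attribute = ga$class, has_type3 = ga$has_type3,
      n_uorfs = sum(u$type != "unterminated"), stringsAsFactors = FALSE)
  }
  list(uorfs = if (length(tabs)) do.call(rbind, tabs) else empty_uorf_df(),
       attributes = if (length(attrs)) do.call(rbind, attrs) else
         data.frame(gene_id = character(), transcript_id = character(),
                    attribute = character(), has_type3 = logical(),
                    n_uorfs = integer()))
}

#' Population-level uORF variant analysis of one gene
#'
#' Applies an accession cohort's filtered homozygous variants to one
#' representative transcript, finds uORFs on each pseudo-cDNA, collects and
#' numbers the forms, classifies per-accession events and computes the
#' stratified frequency table and type transitions.
#'
#' @param tm representative `transcript_model`.
#' @param genome contig vector.
#' @param vset variant set from [read_variants()].
#' @param accessions accession ids to analyze (defaults to all VCF samples).
#' @param groups optional accession grouping from [make_groups()].
#' @param start_codons start-codon set.
#' @return list: `forms` (with identifiers), `events`, `frequencies`,
#'   `transitions`, `attributes` (reference + per accession), `dropped`
#'   (accessions failing the mORF-start screen), `ref_uorfs`.
#' @export
analyze_gene <- function(tm, genome, vset,
                         accessions = colnames(vset$genotypes),
                         groups = NULL, start_codons = "ATG") {
  ref <- spliced_cdna(tm, genome, start_codons)
  ref_uorfs <- find_uorfs(ref, start_codons)
  acc_results <- list(); dropped <- character()
  for (acc in accessions) {
    av <- accession_variants(vset, acc, ref)
    if (!screen_morf_start(ref, av)) {
      dropped <- c(dropped, acc)
      next
    }
    pseudo <- build_pseudo_cdna(ref, av, acc)
    acc_results[[acc]] <- list(pseudo = pseudo,
                               uorfs = find_uorfs(pseudo, start_codons))
  }
  forms <- assign_identifiers(collect_forms(ref_uorfs, ref, acc_results))
  events <- classify_events(ref_uorfs, ref, acc_results)
  ref_attr <- gene_type_attribute(ref_uorfs)$class
  acc_attrs <- vapply(acc_results, function(r)
    gene_type_attribute(r$uorfs)$class, "")
  freq <- if (length(acc_results))
    compute_frequencies(forms, names(acc_results), groups, dropped) else
    list(table = NULL, dropped = dropped)
  trans <- population_transitions(ref_attr, acc_attrs, tm$gene_id)
  list(forms = forms, events = events, frequencies = freq,
       transitions = trans,
       attributes = list(reference = ref_attr, accession = acc_attrs),
       dropped = dropped, ref_uorfs = ref_uorfs)
}

#' Population-level uORF variant analysis over a fixture or dataset
#'
#' Convenience driver binding annotation, genome, VCF and metadata into the
#' full workflow: representative-model selection, per-gene pseudo-cDNA
#' construction, identifier assignment, events, frequencies and transitions.
#'
#' @param fasta,gff3,vcf,metadata input paths (`metadata` optional).
#' @param group_mode "latitude" or "label" (used when metadata is given).
#' @param lat_bin latitude bin width in degrees.
#' @param af_threshold allele-fraction threshold for [read_variants()].
#' @param representative_only analyze representative models only (default) or
#'   every splicing model.
#' @param start_codons start-codon set.
#' @return list with per-gene results (`genes`), pooled `forms`, `events`,
#'   `multi_variant` (from [multi_variant_fraction()]), `transitions`,
#'   splicing-model transitions (`model_transitions`) and the loaded
#'   `annotation`.
#' @export
run_population <- function(fasta, gff3, vcf, metadata = NULL,
                           group_mode = "latitude", lat_bin = 15,
                           af_threshold = 0.90, representative_only = TRUE,
                           start_codons = "ATG") {
  genome <- read_genome(fasta)
  ann <- load_annotation(gff3, genome)
  vset <- read_variants(vcf, af_threshold)
  groups <- NULL
  if (!is.null(metadata)) {
    md <- utils::read.delim(metadata, stringsAsFactors = FALSE)
    groups <- make_groups(md, group_mode, lat_bin)
  }
  reps <- select_representative(ann$models)$representative
  models <- if (representative_only) reps else ann$models
  # splicing-model transitions use every model of the reference
  all_scan <- scan_uorfs(genome, ann$models, start_codons)
  mt <- list()
  for (gid in unique(all_scan$attributes$gene_id)) {
    a <- all_scan$attributes[all_scan$attributes$gene_id == gid, ]
    if (nrow(a) >= 2L)
      mt[[length(mt) + 1L]] <- splicing_model_transitions(
        stats::setNames(a$attribute, a$transcript_id), gid)
  }
  genes <- list()
  for (tm in models) {
    if (tm$leader_len == 0L) next
    genes[[tm$gene_id]] <- analyze_gene(tm, genome, vset, groups = groups,
                                        start_codons = start_codons)
  }
  pooled <- do.call(rbind, lapply(names(genes), function(g) {
    f <- genes[[g]]$forms
    if (nrow(f)) cbind(gene_id = g, f) else NULL
  }))
  events <- do.call(rbind, lapply(names(genes), function(g) {
    e <- genes[[g]]$events
    if (nrow(e)) cbind(gene_id = g, e) else NULL
  }))
  trans <- do.call(rbind, lapply(genes, function(x) x$transitions$calls))
  list(genes = genes, forms = pooled, events = events,
       multi_variant = if (!is.null(pooled)) multi_variant_fraction(pooled)
                       else list(fraction = NA_real_, n_forms = 0L,
                                 n_multi = 0L),
       transitions = trans,
       model_transitions = if (length(mt)) do.call(rbind, mt) else NULL,
       annotation = ann, reference_scan = all_scan)
}

#' Write the standard TSV outputs of a population run
#'
#' Emits `uorf_forms.tsv` (gene, locus anchor, identifier, type, length,
#' causal-variant summary, accession count), `events.tsv`, `transitions.tsv`
#' and one frequency table per gene under `out_dir`, with "." for missing
#' values, plus a JSON run manifest.
#'
#' @param res result of [run_population()].
#' @param out_dir output directory.
#' @param config optional list echoed into the manifest.
#' @return invisible vector of written paths.
#' @export
write_outputs <- function(res, out_dir, config = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dot <- function(df) { df[is.na(df)] <- "."; df }
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(dot(as.data.frame(df)), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(res$forms)) {
    f <- res$forms
    wr(data.frame(gene_id = f$gene_id, locus_anchor = f$anchor,
                  identifier = f$identifier, type = f$type,
                  length_nt = f$length_nt, n_snps = f$n_snps,
                  n_indels = f$n_indels,
                  causal_variant_ids = f$variant_ids,
                  accession_count = vapply(strsplit(f$accessions, ","),
                                           function(x)
                                             sum(x != "REF"), 0L)),
       "uorf_forms.tsv")
  }
  if (!is.null(res$events) && nrow(res$events)) wr(res$events, "events.tsv")
  if (!is.null(res$transitions) && nrow(res$transitions))
    wr(res$transitions, "transitions.tsv")
  if (!is.null(res$model_transitions) && nrow(res$model_transitions))
    wr(res$model_transitions, "model_transitions.tsv")
  for (g in names(res$genes)) {
    ft <- res$genes[[g]]$frequencies$table
    if (!is.null(ft) && nrow(ft)) wr(ft, sprintf("frequencies_%s.tsv", g))
  }
  manifest <- list(package = "uorfvar",
                   version = as.character(utils::packageVersion("uorfvar")),
                   r_version = R.version.string,
                   config = config, outputs = basename(paths),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, file.path(out_dir, "manifest.json")))
}
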