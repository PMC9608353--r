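## Readers and writers for the plain-text interchange formats:
## counts.tsv (genes x samples, spike rows prefixed "ERCC-"), samples.tsv,
## spikes.tsv, truth tables, and standard GMT gene-set files.

#' Write a simulated dataset to a directory
#'
#' Emits `counts.tsv`, `samples.tsv`, `spikes.tsv`, `truth_genes.tsv`,
#' `truth_samples.tsv`, `truth_abundance.tsv` (molecules/worm) and
#' `genesets.gmt` (one record per compartment). Round-trips losslessly
#' through [read_dataset()].
#'
#' @param dataset an `arrest_dataset` from [simulate_timeseries()] or
#'   [simulate_aid()].
#' @param directory output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create directory: %s", directory)
  p <- function(f) file.path(directory, f)
  write_matrix_tsv(dataset$counts, p("counts.tsv"))
  write_tsv(dataset$samples, p("samples.tsv"))
  write_tsv(dataset$spikes[, c("spike_id", "conc_attomol_per_ul", "volume_ul")],
            p("spikes.tsv"))
  write_tsv(dataset$truth$genes, p("truth_genes.tsv"))
  write_tsv(dataset$truth$samples, p("truth_samples.tsv"))
  write_matrix_tsv(dataset$truth$abundance, p("truth_abundance.tsv"),
                   comments = c(unit = "molecules_per_worm"))
  sets <- split(dataset$truth$genes$gene_id, dataset$truth$genes$compartment)
  write_gmt(lapply(names(sets), function(nm)
    gene_set(nm, sets[[nm]], note = "true compartment")), p("genesets.gmt"))
  invisible(directory)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(directory) {
  p <- function(f) file.path(directory, f)
  for (f in c("counts.tsv", "samples.tsv", "spikes.tsv"))
    if (!file.exists(p(f))) stopf("missing file: %s", p(f))
  out <- list(counts = read_counts(p("counts.tsv")),
              samples = read_samples(p("samples.tsv")),
              spikes = read_spikes(p("spikes.tsv")))
  if (file.exists(p("truth_genes.tsv")))
    out$truth <- list(genes = read_tsv(p("truth_genes.tsv")),
                      samples = read_tsv(p("truth_samples.tsv")),
                      abundance = read_matrix_tsv(p("truth_abundance.tsv")))
  out
}

#' Read a gene x sample count table
#'
#' First column gene id, header row of sample ids; spike-in rows carry the
#' `"ERCC-"` prefix. Values must be non-negative integers.
#'
#' @param path TSV file.
#' @return integer matrix with gene row names.
#' @export
read_counts <- function(path) {
  mat <- read_matrix_tsv(path)
  assert_count_matrix(mat)
  storage.mode(mat) <- "integer"
  mat
}

#' @rdname read_counts
#' @export
read_samples <- function(path) {
  df <- read_tsv(path)
  if (!"sample_id" %in% names(df)) stopf("samples table lacks sample_id")
  df
}

#' @rdname read_counts
#' @export
read_spikes <- function(path) {
  df <- read_tsv(path)
  need <- c("spike_id", "conc_attomol_per_ul")
  if (!all(need %in% names(df)))
    stopf("spike table must have columns: %s", paste(need, collapse = ", "))
  if (any(df$conc_attomol_per_ul <= 0))
    stopf("spike concentrations must be positive")
  df
}

#' Gene sets and GMT files
#'
#' A gene set is a name, a unique member list, and a free-text provenance
#' note (carried in the GMT description field).
#'
#' @param name set name.
#' @param genes character vector of member gene ids.
#' @param note provenance note.
#' @return list of class `gene_set`.
#' @export
gene_set <- function(name, genes, note = "") {
  structure(list(name = name, genes = unique(as.character(genes)),
                 note = note), class = "gene_set")
}

#' @param sets list of `gene_set` objects.
#' @param path GMT file path.
#' @rdname gene_set
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$note, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname gene_set
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT record: %s", substr(l, 1, 40))
    gene_set(f[1], f[-(1:2)], note = f[2])
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}
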