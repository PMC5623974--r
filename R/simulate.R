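# End-to-end simulation: mutate the reference, add fusion contigs, simulate
# paired-end reads, lift the truth back to original coordinates, and write
# the dataset (FASTQ + truth files + manifest).

#' Simulate a truth-annotated RNA-seq dataset
#'
#' Runs the full workflow: random and VCF-guided SNV/indel injection at the
#' configured per-base rates with overlap resolution, construction of the
#' haploid mutated genome and its coordinate map, fusion-gene generation,
#' expression-profile drawing, paired-end read simulation with substitution
#' errors, liftover of every read alignment to original-reference
#' coordinates, and truth encoding in the read names.
#'
#' @param genome Named character vector of reference sequences.
#' @param annotation Annotation tibble (see [read_gtf()]).
#' @param vcf Optional path to a VCF of known biallelic variants.
#' @param snv_rate Per-base SNV rate (default 0.0014, the normal-tissue
#'   setting; use 0.0016 for the somatic setting).
#' @param ins_rate,del_rate Per-base insertion/deletion rates (default 1e-4).
#' @param max_indel_len Maximum indel length (default 15).
#' @param vcf_ratio Fraction of mutations taken from the VCF when `vcf` is
#'   supplied (default 0.95).
#' @param n_fusions Number of fusion genes to introduce (default 0; the
#'   somatic setting uses 100).
#' @param read_length Read length in bases (default 101).
#' @param n_read_pairs Number of read pairs to simulate.
#' @param fragment_mean,fragment_sd Fragment length distribution (250/50).
#' @param error_rate Per-base substitution sequencing-error rate (0.001).
#' @param k,x0,x1,n_molecules Expression-law parameters, see
#'   [draw_expression_profile()].
#' @param colinear_threshold Colinear fusion span threshold (300 kb).
#' @param seed Optional integer seed for full reproducibility.
#' @param outdir Optional directory; when given, the dataset is written
#'   there with [write_dataset()].
#' @return List of class `sim_dataset` with the original and mutated
#'   genomes, applied mutations, coordinate map, fusion model, reads,
#'   lifted records, encoded names, truth database and the parameters used.
#' @export
simulate_dataset <- function(genome, annotation, vcf = NULL,
                             snv_rate = 0.0014, ins_rate = 1e-4,
                             del_rate = 1e-4, max_indel_len = 15L,
                             vcf_ratio = 0.95, n_fusions = 0L,
                             read_length = 101L, n_read_pairs = 10000L,
                             fragment_mean = 250, fragment_sd = 50,
                             error_rate = 0.001, k = -0.7, x0 = 15000,
                             x1 = x0^2, n_molecules = 1e6,
                             colinear_threshold = 300000L,
                             seed = NULL, outdir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_annotation(annotation, genome)

  random_pool <- dplyr::bind_rows(
    generate_random_snvs(genome, snv_rate),
    generate_random_indels(genome, ins_rate, del_rate, max_indel_len)
  )
  if (!is.null(vcf)) {
    vcf_pool <- load_vcf_mutations(vcf, genome)
    candidates <- mix_sources(vcf_pool, random_pool, vcf_ratio)
  } else {
    candidates <- random_pool
  }
  mutations <- resolve_overlaps(candidates)

  applied <- apply_mutations(genome, mutations)
  sim_annotation <- shift_annotations(annotation, applied$map)

  fus <- generate_fusions(genome, annotation, n_fusions)
  sim_genome <- c(applied$genome, fus$contigs)
  sim_annotation <- dplyr::bind_rows(sim_annotation, fus$annotation)

  tx_seqs <- transcript_sequences(sim_genome, sim_annotation)
  profile <- draw_expression_profile(names(tx_seqs), k = k, x0 = x0, x1 = x1,
                                     n_molecules = n_molecules)
  fragments <- fragment_and_sample(profile, tx_seqs, n_read_pairs,
                                   read_length, fragment_mean, fragment_sd)
  reads <- make_read_pairs(fragments, tx_seqs, read_length, error_rate)
  projections <- project_to_genome(reads, sim_annotation, read_length)
  records <- lift_alignment(projections, applied$map, fus$registry)
  names_ <- encode_dataset_names(reads, records, read_length)
  truth <- build_truth_db(records, mutations, colinear_threshold)

  params <- list(
    snv_rate = snv_rate, ins_rate = ins_rate, del_rate = del_rate,
    max_indel_len = max_indel_len, vcf_ratio = vcf_ratio,
    n_fusions = n_fusions, read_length = read_length,
    n_read_pairs = n_read_pairs, fragment_mean = fragment_mean,
    fragment_sd = fragment_sd, error_rate = error_rate, k = k, x0 = x0,
    x1 = x1, n_molecules = n_molecules,
    colinear_threshold = colinear_threshold, seed = seed
  )
  ds <- structure(list(
    genome = genome, mutated_genome = applied$genome, map = applied$map,
    mutations = mutations, fusions = fus, profile = profile,
    reads = reads, records = records, names = names_, truth = truth,
    params = params
  ), class = "sim_dataset")
  if (!is.null(outdir)) write_dataset(ds, outdir)
  ds
}

#' @exportS3Method base::print
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", nrow(x$reads), " read pairs, ",
      nrow(x$mutations), " mutations, ", length(x$fusions$contigs),
      " fusion contig(s)\n", sep = "")
  print(x$truth)
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes paired FASTQ files (`reads_1.fastq` / `reads_2.fastq`, identical
#' truth-encoded names per pair, constant quality `I`), the truth files
#' (`mutations.tsv`, `mutations.vcf`, `splices.bed` as BED6 with 0-based
#' half-open intron coordinates, `fusions.tsv`) and `manifest.json`
#' recording the parameters, seed, chromosome lengths and per-event totals.
#'
#' @param dataset A `sim_dataset` from [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rl <- dataset$params$read_length
  qual <- strrep("I", rl)
  n <- nrow(dataset$reads)
  fq <- function(seqs, path) {
    lines <- character(4L * n)
    lines[seq(1, length.out = n, by = 4)] <- paste0("@", dataset$names)
    lines[seq(2, length.out = n, by = 4)] <- seqs
    lines[seq(3, length.out = n, by = 4)] <- "+"
    lines[seq(4, length.out = n, by = 4)] <- qual
    writeLines(lines, path)
  }
  fq(dataset$reads$seq1, file.path(outdir, "reads_1.fastq"))
  fq(dataset$reads$seq2, file.path(outdir, "reads_2.fastq"))

  truth <- dataset$truth
  readr::write_tsv(truth$mutations, file.path(outdir, "mutations.tsv"))
  write_vcf(truth$mutations, file.path(outdir, "mutations.vcf"), dataset$genome)
  bed <- truth$splices
  bed_lines <- sprintf("%s\t%d\t%d\tjunc_%d\t%d\t%s", bed$chrom, bed$start - 1L,
                       bed$end, seq_len(nrow(bed)), bed$support, bed$strand)
  writeLines(bed_lines, file.path(outdir, "splices.bed"))
  readr::write_tsv(truth$fusions, file.path(outdir, "fusions.tsv"))

  manifest <- list(
    tool = "simbench",
    params = dataset$params,
    chrom_lengths = as.list(vapply(dataset$genome, nchar, integer(1))),
    n_read_pairs = n,
    counts = list(
      snv = sum(truth$mutations$kind == "SNV"),
      insertion = sum(truth$mutations$kind == "INS"),
      deletion = sum(truth$mutations$kind == "DEL"),
      splice = nrow(truth$splices),
      colinear_fusion = sum(truth$fusions$class == "COLINEAR_FUSION"),
      noncolinear_fusion = sum(truth$fusions$class == "NONCOLINEAR_FUSION")
    )
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' Read a truth database back from a dataset directory
#'
#' @param dir Dataset directory written by [write_dataset()].
#' @return List of class `truth_db` with `mutations`, `splices`, `fusions`,
#'   plus `n_read_pairs` and `chrom_lengths` from the manifest and the FASTQ
#'   read names in `names`.
#' @export
read_truth_db <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  mut <- readr::read_tsv(file.path(dir, "mutations.tsv"),
                         col_types = readr::cols(
                           kind = "c", chrom = "c", pos = "i", ref = "c",
                           alt = "c", source = "c", support = "i"))
  mut$ref[is.na(mut$ref)] <- ""
  mut$alt[is.na(mut$alt)] <- ""
  bed_path <- file.path(dir, "splices.bed")
  bed_lines <- readLines(bed_path)
  if (length(bed_lines) > 0) {
    f <- strsplit(bed_lines, "\t", fixed = TRUE)
    splices <- tibble::tibble(
      chrom = vapply(f, `[[`, character(1), 1),
      start = as.integer(vapply(f, `[[`, character(1), 2)) + 1L,
      end = as.integer(vapply(f, `[[`, character(1), 3)),
      strand = vapply(f, `[[`, character(1), 6),
      support = as.integer(vapply(f, `[[`, character(1), 5))
    )
  } else {
    splices <- tibble::tibble(chrom = character(), start = integer(),
                              end = integer(), strand = character(),
                              support = integer())
  }
  fusions <- readr::read_tsv(file.path(dir, "fusions.tsv"),
                             col_types = readr::cols(
                               chrom1 = "c", pos1 = "i", strand1 = "c",
                               chrom2 = "c", pos2 = "i", strand2 = "c",
                               class = "c", support = "i"))
  fq <- readLines(file.path(dir, "reads_1.fastq"))
  names_ <- sub("^@", "", fq[seq(1, length.out = length(fq) %/% 4, by = 4)])
  structure(list(
    mutations = mut, splices = splices, fusions = fusions,
    names = names_,
    n_read_pairs = manifest$n_read_pairs,
    chrom_lengths = unlist(manifest$chrom_lengths)
  ), class = "truth_db")
}

#' Generate a toy genome, annotation and VCF for testing and demonstration
#'
#' Builds a random genome with the requested chromosome sizes, places
#' non-overlapping multi-exon gene models on random strands (a fraction of
#' genes get a second, shorter transcript), and optionally samples biallelic
#' VCF sites consistent with the genome.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param n_genes Number of genes to place.
#' @param n_vcf_sites Number of biallelic VCF records to sample (0 for none).
#' @param exons_per_gene Range (min, max) of exons per transcript.
#' @param seed Optional integer seed.
#' @return List with `genome` (named character), `annotation` (tibble) and
#'   `vcf` (mutation tibble, or `NULL`).
#' @export
make_fixture <- function(chrom_sizes = c(chr1 = 100000L, chr2 = 100000L),
                         n_genes = 50L, n_vcf_sites = 0L,
                         exons_per_gene = c(2L, 5L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome <- vapply(chrom_sizes, random_dna, character(1))
  names(genome) <- names(chrom_sizes)

  ann <- list()
  gene_i <- 0L
  cursors <- stats::setNames(rep(1L, length(genome)), names(genome))
  chroms <- rep(names(genome), length.out = n_genes * 3)
  for (chrom in sample(chroms)) {
    if (gene_i >= n_genes) break
    n_ex <- sample(seq(exons_per_gene[1], exons_per_gene[2]), 1)
    ex_len <- sample(80:300, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1) sample(60:400, n_ex - 1, replace = TRUE) else integer(0)
    gstart <- cursors[[chrom]] + sample(200:800, 1)
    starts <- gstart + cumsum(c(0L, ex_len[-n_ex] + in_len))
    ends <- starts + ex_len - 1L
    if (ends[n_ex] > chrom_sizes[[chrom]]) next
    gene_i <- gene_i + 1L
    gid <- sprintf("gene_%03d", gene_i)
    strand <- sample(c("+", "-"), 1)
    ann[[length(ann) + 1]] <- tibble::tibble(
      gene_id = gid, transcript_id = paste0(gid, "_t1"), chrom = chrom,
      strand = strand, start = as.integer(starts), end = as.integer(ends))
    if (n_ex >= 3 && stats::runif(1) < 0.2) {
      keep <- sort(sample(n_ex, n_ex - 1))
      ann[[length(ann) + 1]] <- tibble::tibble(
        gene_id = gid, transcript_id = paste0(gid, "_t2"), chrom = chrom,
        strand = strand, start = as.integer(starts[keep]),
        end = as.integer(ends[keep]))
    }
    cursors[[chrom]] <- ends[n_ex]
  }
  if (gene_i < n_genes) {
    stop("Could not place ", n_genes, " genes on the requested chromosomes")
  }
  annotation <- dplyr::bind_rows(ann)

  vcf <- NULL
  if (n_vcf_sites > 0) {
    # Oversample a pool at a matching density, then thin to the exact count.
    rate <- min(0.4, 1.5 * n_vcf_sites / sum(chrom_sizes))
    vcf <- dplyr::bind_rows(
      generate_random_snvs(genome, 0.9 * rate),
      generate_random_indels(genome, 0.05 * rate, 0.05 * rate)
    )
    vcf <- resolve_overlaps(vcf)
    if (nrow(vcf) < n_vcf_sites) {
      stop("VCF site pool came out smaller than requested; ask for fewer sites")
    }
    vcf <- vcf[sort(sample(nrow(vcf), n_vcf_sites)), ]
    vcf$source <- "vcf"
  }
  list(genome = genome, annotation = annotation, vcf = vcf)
}
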