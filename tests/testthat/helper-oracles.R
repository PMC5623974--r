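# Independent oracles used by the property and acceptance tests. These
# deliberately re-derive results with naive algorithms (per-position vectors,
# string edits, all-pairs scans) rather than calling the package's own
# interval/segment machinery.

# Per-position map of a mutated chromosome built by naive string edits:
# returns list(seq = mutated sequence, orig = integer vector giving, for
# every mutated position, its original coordinate (NA inside insertions),
# anchor = insertion anchor for NA positions.
brute_mutate <- function(seq, muts) {
  muts <- muts[order(muts$pos), ]
  orig <- seq_len(nchar(seq))
  anchor <- rep(NA_integer_, nchar(seq))
  chars <- strsplit(seq, "")[[1]]
  # Apply from right to left so earlier coordinates stay valid.
  for (i in rev(seq_len(nrow(muts)))) {
    p <- muts$pos[i]
    if (muts$kind[i] == "SNV") {
      chars[p] <- muts$alt[i]
    } else if (muts$kind[i] == "INS") {
      ins <- strsplit(muts$alt[i], "")[[1]]
      chars <- append(chars, ins, after = p)
      orig <- append(orig, rep(NA_integer_, length(ins)), after = p)
      anchor <- append(anchor, rep(p, length(ins)), after = p)
    } else {
      k <- nchar(muts$ref[i])
      chars <- chars[-(p:(p + k - 1))]
      orig <- orig[-(p:(p + k - 1))]
      anchor <- anchor[-(p:(p + k - 1))]
    }
  }
  list(seq = paste(chars, collapse = ""), orig = orig, anchor = anchor)
}

# Walk a CIGAR over the original genome, substituting the known mutation
# alleles, and return the read-order sequence the record claims ("?" for
# soft-clipped bases). Errors are not applied.
oracle_read_from_record <- function(chrom, pos, strand, cigar, genome, muts) {
  m <- muts[muts$chrom == chrom, ]
  snv_alt <- stats::setNames(m$alt[m$kind == "SNV"], m$pos[m$kind == "SNV"])
  ins_alt <- stats::setNames(m$alt[m$kind == "INS"], m$pos[m$kind == "INS"])
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNS]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNS]", "", ops))
  what <- sub("\\d+", "", ops)
  cur <- pos
  out <- character(0)
  for (j in seq_along(ops)) {
    if (what[j] == "M") {
      bases <- strsplit(substring(genome[[chrom]], cur, cur + lens[j] - 1), "")[[1]]
      hit <- as.character(cur:(cur + lens[j] - 1)) %in% names(snv_alt)
      bases[hit] <- snv_alt[as.character((cur:(cur + lens[j] - 1))[hit])]
      out <- c(out, bases)
      cur <- cur + lens[j]
    } else if (what[j] %in% c("D", "N")) {
      cur <- cur + lens[j]
    } else if (what[j] == "I") {
      alt <- ins_alt[as.character(cur - 1L)]
      bases <- if (is.na(alt)) rep("?", lens[j]) else strsplit(alt, "")[[1]]
      if (length(bases) != lens[j]) bases <- rep("?", lens[j])
      out <- c(out, bases)
    } else { # S
      out <- c(out, rep("?", lens[j]))
    }
  }
  s <- paste(out, collapse = "")
  if (strand == "-") {
    s <- paste(rev(strsplit(chartr("ACGT?", "TGCA?", s), "")[[1]]), collapse = "")
  }
  s
}

# Reference intervals (M/D/N walk) of one decoded alignment record.
oracle_ref_ops <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNS]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNS]", "", ops))
  what <- sub("\\d+", "", ops)
  cur <- pos
  rows <- list()
  for (j in seq_along(ops)) {
    if (what[j] %in% c("M", "D", "N")) {
      rows[[j]] <- data.frame(op = what[j], len = lens[j], start = cur,
                              end = cur + lens[j] - 1)
      cur <- cur + lens[j]
    } else {
      rows[[j]] <- data.frame(op = what[j], len = lens[j], start = NA,
                              end = NA)
    }
  }
  do.call(rbind, rows)
}

# All-pairs brute-force splice evaluator implementing the matching rules
# with plain loops (no interval tree).
oracle_eval_splices <- function(pred, truth, threshold) {
  consumed <- rep(FALSE, nrow(truth))
  tp <- 0L; fp <- 0L
  for (i in seq_len(nrow(pred))) {
    best <- NA_integer_; best_d <- Inf
    for (j in seq_len(nrow(truth))) {
      same <- truth$chrom[j] == pred$chrom[i] &&
        (truth$strand[j] %in% c(".", "*") || pred$strand[i] %in% c(".", "*") ||
           truth$strand[j] == pred$strand[i])
      overlap <- same && truth$start[j] <= pred$end[i] &&
        truth$end[j] >= pred$start[i]
      if (!overlap) next
      d <- abs(pred$start[i] - truth$start[j]) + abs(pred$end[i] - truth$end[j])
      if (d < best_d) { best_d <- d; best <- j }
    }
    if (is.na(best) || best_d > threshold) {
      fp <- fp + 1L
    } else if (!consumed[best]) {
      consumed[best] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = fp, fn = nrow(truth) - sum(consumed))
}

oracle_eval_mutations <- function(pred, truth, kind, threshold) {
  pred <- pred[pred$kind == kind, , drop = FALSE]
  truth <- truth[truth$kind == kind, , drop = FALSE]
  plen <- ifelse(pred$kind == "INS", nchar(pred$alt), nchar(pred$ref))
  tlen <- ifelse(truth$kind == "INS", nchar(truth$alt), nchar(truth$ref))
  consumed <- rep(FALSE, nrow(truth))
  tp <- 0L; fp <- 0L
  for (i in seq_len(nrow(pred))) {
    best <- NA_integer_; best_d <- Inf
    for (j in seq_len(nrow(truth))) {
      if (truth$chrom[j] != pred$chrom[i]) next
      d <- abs(pred$pos[i] - truth$pos[j])
      if (d <= threshold && d < best_d) { best_d <- d; best <- j }
    }
    ok <- !is.na(best)
    if (ok && kind == "SNV") ok <- pred$alt[i] == truth$alt[best]
    if (ok && kind != "SNV") ok <- abs(plen[i] - tlen[best]) <= threshold
    if (!ok) {
      fp <- fp + 1L
    } else if (!consumed[best]) {
      consumed[best] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = fp, fn = nrow(truth) - sum(consumed))
}

oracle_eval_fusions <- function(pred, truth, chrom_lengths, threshold) {
  canon <- function(df) {
    for (i in seq_len(nrow(df))) {
      if (df$chrom2[i] < df$chrom1[i] ||
          (df$chrom2[i] == df$chrom1[i] && df$pos2[i] < df$pos1[i])) {
        df[i, c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")] <-
          data.frame(df$chrom2[i], df$pos2[i],
                     ifelse(df$strand2[i] == "+", "-", "+"),
                     df$chrom1[i], df$pos1[i],
                     ifelse(df$strand1[i] == "+", "-", "+"))
      }
    }
    df
  }
  pred <- canon(pred); truth <- canon(truth)
  consumed <- rep(FALSE, nrow(truth))
  tp <- 0L; fp <- 0L
  for (i in seq_len(nrow(pred))) {
    best <- NA_integer_; best_d <- Inf
    for (j in seq_len(nrow(truth))) {
      if (truth$chrom1[j] != pred$chrom1[i] ||
          truth$chrom2[j] != pred$chrom2[i] ||
          truth$strand1[j] != pred$strand1[i] ||
          truth$strand2[j] != pred$strand2[i]) next
      d <- abs(pred$pos1[i] - truth$pos1[j]) + abs(pred$pos2[i] - truth$pos2[j])
      if (d <= threshold && d < best_d) { best_d <- d; best <- j }
    }
    if (is.na(best)) {
      fp <- fp + 1L
    } else if (!consumed[best]) {
      consumed[best] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = fp, fn = nrow(truth) - sum(consumed))
}

# Random evaluation-set generators for the oracle-equivalence properties.
random_splice_set <- function(n_truth, n_pred, chroms = c("c1", "c2")) {
  truth <- tibble::tibble(
    chrom = sample(chroms, n_truth, TRUE),
    start = sample.int(5000, n_truth, TRUE),
    strand = sample(c("+", "-"), n_truth, TRUE)
  )
  truth$end <- truth$start + sample(50:500, n_truth, TRUE)
  base <- truth[sample.int(n_truth, n_pred, TRUE), ]
  pred <- tibble::tibble(
    chrom = base$chrom,
    start = base$start + sample(-15:15, n_pred, TRUE),
    end = base$end + sample(-15:15, n_pred, TRUE),
    strand = ifelse(stats::runif(n_pred) < 0.9, base$strand,
                    sample(c("+", "-"), n_pred, TRUE))
  )
  miss <- stats::runif(n_pred) < 0.2
  pred$start[miss] <- pred$start[miss] + 3000L
  pred$end[miss] <- pred$end[miss] + 3000L
  list(truth = truth, pred = pred)
}

random_mutation_set <- function(n_truth, n_pred, kind) {
  mk_allele <- function(n, len) {
    vapply(len, function(l) paste(sample(c("A", "C", "G", "T"), l, TRUE),
                                  collapse = ""), character(1))
  }
  ref <- switch(kind,
                DEL = mk_allele(n_truth, sample(1:15, n_truth, TRUE)),
                SNV = mk_allele(n_truth, rep(1, n_truth)),
                INS = rep("", n_truth))
  alt <- switch(kind,
                INS = mk_allele(n_truth, sample(1:15, n_truth, TRUE)),
                SNV = mk_allele(n_truth, rep(1, n_truth)),
                DEL = rep("", n_truth))
  truth <- tibble::tibble(
    kind = kind,
    chrom = sample(c("c1", "c2"), n_truth, TRUE),
    pos = sample.int(20000, n_truth, TRUE),
    ref = ref,
    alt = alt,
    source = "random"
  )
  base <- truth[sample.int(n_truth, n_pred, TRUE), ]
  pred <- base
  pred$pos <- base$pos + sample(-8:8, n_pred, TRUE)
  flip <- stats::runif(n_pred) < 0.3
  if (kind == "SNV") pred$alt[flip] <- mk_allele(sum(flip), rep(1, sum(flip)))
  if (kind == "INS") pred$alt[flip] <- mk_allele(sum(flip), sample(1:15, sum(flip), TRUE))
  if (kind == "DEL") pred$ref[flip] <- mk_allele(sum(flip), sample(1:15, sum(flip), TRUE))
  miss <- stats::runif(n_pred) < 0.2
  pred$pos[miss] <- pred$pos[miss] + 1000L
  list(truth = truth, pred = pred[, c("chrom", "pos", "ref", "alt", "kind")])
}

random_fusion_set <- function(n_truth, n_pred,
                              chrom_lengths = c(c1 = 100000L, c2 = 100000L)) {
  truth <- tibble::tibble(
    chrom1 = sample(names(chrom_lengths), n_truth, TRUE),
    pos1 = sample.int(90000, n_truth, TRUE),
    strand1 = sample(c("+", "-"), n_truth, TRUE),
    chrom2 = sample(names(chrom_lengths), n_truth, TRUE),
    pos2 = sample.int(90000, n_truth, TRUE),
    strand2 = sample(c("+", "-"), n_truth, TRUE),
    class = "NONCOLINEAR_FUSION"
  )
  base <- truth[sample.int(n_truth, n_pred, TRUE), ]
  pred <- base[, 1:6]
  pred$pos1 <- base$pos1 + sample(-15:15, n_pred, TRUE)
  pred$pos2 <- base$pos2 + sample(-15:15, n_pred, TRUE)
  rev_idx <- stats::runif(n_pred) < 0.3   # report the junction reversed
  if (any(rev_idx)) {
    tmp <- pred[rev_idx, ]
    pred[rev_idx, ] <- tibble::tibble(
      chrom1 = tmp$chrom2, pos1 = tmp$pos2,
      strand1 = ifelse(tmp$strand2 == "+", "-", "+"),
      chrom2 = tmp$chrom1, pos2 = tmp$pos1,
      strand2 = ifelse(tmp$strand1 == "+", "-", "+"))
  }
  miss <- stats::runif(n_pred) < 0.2
  pred$pos1[miss] <- pred$pos1[miss] + 5000L
  list(truth = truth, pred = pred, chrom_lengths = chrom_lengths)
}
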