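# Shared fixtures built in code. Expensive objects (fixtures and pipeline
# runs) are generated once per session and cached.

.jf_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .jf_cache)) {
    assign(name, force(expr), envir = .jf_cache)
  }
  get(name, envir = .jf_cache)
}

# standard study-condition fixture at full scale
default_fixture <- function(seed = 1L) {
  cached(paste0("fixture_", seed), generate_fixture(fixture_spec(seed = seed)))
}

default_run <- function(seed = 1L) {
  cached(paste0("run_", seed), {
    fx <- default_fixture(seed)
    run_full(fx$paths$sam, fx$paths$genome, pipeline_config(seed = seed))
  })
}

# quick fixture for structural tests
small_fixture <- function(seed = 11L) {
  cached(paste0("small_fixture_", seed), generate_fixture(fixture_spec(
    seed = seed, n_genuine = 40L,
    n_spurious = c(low_entropy = 10L, non_canonical = 10L,
                   repeat_induced = 10L, single_read = 10L),
    coverage = 12L)))
}

small_run <- function(seed = 11L) {
  cached(paste0("small_run_", seed), {
    fx <- small_fixture(seed)
    run_full(fx$paths$sam, fx$paths$genome, pipeline_config(seed = seed))
  })
}

# write a genome FASTA from a named character vector
write_test_genome <- function(seqs, path = tempfile(fileext = ".fa")) {
  lines <- unlist(lapply(names(seqs), function(nm) c(paste0(">", nm),
                                                     seqs[[nm]])))
  writeLines(lines, path)
  path
}

# write a minimal SAM over the given contigs; reads is a data.frame with
# qname, flag, rname, pos (1-based), mapq, cigar, seq and optional nm, nh
write_test_sam <- function(seqs, reads, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(seqs), "\tLN:", nchar(seqs)))
  reads <- reads[order(reads$rname, reads$pos), , drop = FALSE]
  body <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    tags <- character(0)
    if (!is.null(r$nm) && !is.na(r$nm)) tags <- c(tags, paste0("NM:i:", r$nm))
    if (!is.null(r$nh) && !is.na(r$nh)) tags <- c(tags, paste0("NH:i:", r$nh))
    paste(c(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar, "*", 0, 0,
            r$seq, strrep("I", nchar(r$seq)), tags), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# build the spliced read sequence matching the genome over a junction
spliced_seq <- function(seqs, contig, pos1, cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub(".$", "", ops))
  opch <- substr(ops, nchar(ops), nchar(ops))
  rpos <- pos1 - 1
  out <- ""
  for (k in seq_along(lens)) {
    if (opch[k] %in% c("M", "=", "X")) {
      out <- paste0(out, substr(seqs[[contig]], rpos + 1, rpos + lens[k]))
      rpos <- rpos + lens[k]
    } else if (opch[k] %in% c("D", "N")) {
      rpos <- rpos + lens[k]
    }
  }
  out
}

# deterministic random genome for hand-built alignment tests
test_genome_seqs <- function(len = 3000L, n = 1L, seed = 5L) {
  set.seed(seed)
  stats::setNames(
    vapply(seq_len(n), function(i)
      paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = ""), character(1)),
    paste0("chr", seq_len(n)))
}

extract_from_sam <- function(seqs, reads, min_intron = 4L,
                             max_intron = 500000L, ...) {
  g <- write_test_genome(seqs)
  s <- write_test_sam(seqs, reads)
  prep <- prepare(s, g)
  iterate_split_reads(prep, min_intron = min_intron,
                      max_intron = max_intron, ...)
}
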