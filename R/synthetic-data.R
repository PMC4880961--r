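#' @include AllClasses.R utils.R
NULL

## default insert length weights: the canonical plant sRNA profile with a
## dominant 24-nt class and a secondary 21-nt class; the remaining lengths
## share the residual mass equally.
.defaultLengthWeights <- function() {
    w <- setNames(rep(0, 16), as.character(15:30))
    w["24"] <- 0.50; w["21"] <- 0.218; w["23"] <- 0.0895
    w["20"] <- 0.0693; w["22"] <- 0.0631
    rest <- names(w)[w == 0]
    w[rest] <- (1 - sum(w)) / length(rest)
    w
}

## default 5'-U fraction per length class: strong U preference for the
## miRNA-sized classes, an A-shifted 18-nt class, weak bias elsewhere.
.defaultFirstBaseU <- function() {
    u <- setNames(rep(0.8, 16), as.character(15:30))
    u[c("15", "16", "17")] <- 0.25
    u["18"] <- 0.15
    u["24"] <- 0.95
    u[as.character(27:30)] <- 0.5
    u
}

#' Configuration for the synthetic small RNA read generator
#'
#' Bundles and validates every knob of \code{\link{generateReads}}.  The
#' default category fractions reproduce the removal profile of a typical
#' deep plant sRNA library (clean reads dominating at ~99 percent, with
#' small adapter-null, insert-null, 5'-contaminant, short and polyA
#' fractions); the default length weights put half the mass at 24 nt with
#' a secondary 21-nt mode, and the default first-base bias prefers U
#' except for the A-shifted 18-nt class.  Adapter defaults are the
#' standard Illumina small RNA adapter sequences.
#'
#' @param n_reads number of reads to generate
#' @param seed integer seed; identical configs give byte-identical FASTQ
#' @param adapter3,adapter5 adapter sequences (DNA alphabet)
#' @param category_fractions named fractions over the six read categories
#'   (\code{clean}, \code{adapter3_null}, \code{insert_null},
#'   \code{adapter5_contam}, \code{short_lt18}, \code{polyA}); must sum
#'   to 1
#' @param length_weights named fractions over insert lengths 15-30; must
#'   sum to 1
#' @param spike_mirnas \code{NULL}, or a data.frame with columns
#'   \code{name}, \code{seq}, \code{abundance}: mature miRNA sequences
#'   spiked into the clean fraction with the given relative abundances
#' @param spike_fraction fraction of clean reads drawn from the spikes
#' @param first_base_u_fraction named per-length probability that a
#'   background insert starts with U
#' @param read_length sequencer read length in cycles
#' @return a validated \code{GeneratorConfig} (list with class attribute)
#' @export
generatorConfig <- function(n_reads = 20000L,
                            seed = 1L,
                            adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                            adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                            category_fractions = c(
                                clean = 0.99137, adapter3_null = 0.00146,
                                insert_null = 0.00017,
                                adapter5_contam = 0.00308,
                                short_lt18 = 0.00387, polyA = 0.00005),
                            length_weights = .defaultLengthWeights(),
                            spike_mirnas = NULL,
                            spike_fraction = 0.24,
                            first_base_u_fraction = .defaultFirstBaseU(),
                            read_length = 50L) {
    if (n_reads < 0) stop("n_reads must be >= 0")
    .checkAlphabet(.toDna(adapter3), what = "adapter3")
    .checkAlphabet(.toDna(adapter5), what = "adapter5")
    if (!setequal(names(category_fractions), .CLEAN_CATEGORIES))
        stop("category_fractions must be named exactly: ",
             paste(.CLEAN_CATEGORIES, collapse = ", "))
    if (any(category_fractions < 0) || any(category_fractions > 1))
        stop("category fractions must lie in [0, 1]")
    if (abs(sum(category_fractions) - 1) > 1e-9)
        stop("category_fractions must sum to 1 (got ",
             sum(category_fractions), ")")
    if (abs(sum(length_weights) - 1) > 1e-9)
        stop("length_weights must sum to 1")
    if (!all(as.character(15:30) %in% names(length_weights)))
        stop("length_weights must cover lengths 15-30")
    if (!is.null(spike_mirnas)) {
        stopifnot(is.data.frame(spike_mirnas),
                  all(c("name", "seq", "abundance") %in%
                      colnames(spike_mirnas)))
        spike_mirnas$seq <- .toDna(spike_mirnas$seq)
        .checkAlphabet(spike_mirnas$seq, what = "spike miRNA")
    }
    if (spike_fraction < 0 || spike_fraction > 1)
        stop("spike_fraction must lie in [0, 1]")
    structure(list(n_reads = as.integer(n_reads), seed = as.integer(seed),
                   adapter3 = .toDna(adapter3), adapter5 = .toDna(adapter5),
                   category_fractions = category_fractions,
                   length_weights = length_weights,
                   spike_mirnas = spike_mirnas,
                   spike_fraction = spike_fraction,
                   first_base_u_fraction = first_base_u_fraction,
                   read_length = as.integer(read_length)),
              class = "GeneratorConfig")
}

## a background insert is "safe" if the cleaner will classify it as clean:
## no internal 3'-adapter seed hit, no 5'-adapter prefix, not polyA-like
.insertUnsafe <- function(x, adapter3, adapter5, polyA_threshold = 0.9) {
    seed3 <- substr(adapter3, 1, 8)
    seed5 <- substr(adapter5, 1, 8)
    bad <- rep(FALSE, length(x))
    for (s in seq_len(max(nchar(x)) - 7L)) {
        mm <- .prefixMismatches(x, seed3, from = s)
        bad <- bad | (!is.na(mm) & mm <= 1L)
    }
    mm5 <- .prefixMismatches(x, seed5, from = 1L)
    bad <- bad | (!is.na(mm5) & mm5 <= 1L)
    fracA <- vapply(strsplit(x, ""), function(b) mean(b == "A"),
                    numeric(1))
    bad | (fracA >= polyA_threshold)
}

.safeBackgroundInserts <- function(n, lens, ufrac, adapter3, adapter5) {
    if (n == 0L) return(character(0))
    first <- ifelse(runif(n) < ufrac[as.character(lens)], "T", NA)
    out <- vapply(seq_len(n), function(i) {
        s <- sample(c("A", "C", "G", "T"), lens[i], replace = TRUE)
        if (!is.na(first[i])) s[1] <- "T"
        else s[1] <- sample(c("A", "C", "G"), 1L)
        paste(s, collapse = "")
    }, character(1))
    repeat {
        bad <- .insertUnsafe(out, adapter3, adapter5)
        if (!any(bad)) break
        out[bad] <- vapply(which(bad), function(i) {
            s <- sample(c("A", "C", "G", "T"), lens[i], replace = TRUE)
            paste(s, collapse = "")
        }, character(1))
    }
    out
}

#' Generate a labelled synthetic small RNA FASTQ library
#'
#' Emulates an adapter-ligated small RNA sequencing library: clean reads
#' are an insert (spiked mature miRNA or biased background sequence)
#' followed by the 3' adapter; the five removal categories are constructed
#' so that \code{\link{cleanReads}} assigns each read to its true label.
#' The truth table records every read's category and source.
#'
#' @param config a \code{\link{generatorConfig}}
#' @param fastq optional path; when given, reads are written as
#'   Sanger/Phred+33 FASTQ (byte-identical across runs with equal config)
#' @param truth optional path for the tab-separated truth table
#' @return list with \code{reads} (data.frame: id, seq, qual),
#'   \code{truth} (data.frame: id, category, source) and the file paths
#' @export
generateReads <- function(config, fastq = NULL, truth = NULL) {
    stopifnot(inherits(config, "GeneratorConfig"))
    set.seed(config$seed)
    n <- config$n_reads
    rl <- config$read_length
    a3 <- config$adapter3; a5 <- config$adapter5
    cats <- if (n > 0)
        sample(names(config$category_fractions), n, replace = TRUE,
               prob = config$category_fractions) else character(0)
    seqs <- character(n)
    src <- rep("background", n)

    pad <- function(core, m) {
        short <- nchar(core) < rl
        if (any(short)) {
            need <- rl - nchar(core[short])
            core[short] <- paste0(core[short],
                                  .randSeq(sum(short), need))
        }
        substr(core, 1, rl)
    }

    idx <- which(cats == "clean")
    if (length(idx)) {
        lw <- config$length_weights
        keep <- as.integer(names(lw)) >= 18
        lens <- as.integer(sample(names(lw)[keep], length(idx),
                                  replace = TRUE,
                                  prob = lw[keep] / sum(lw[keep])))
        spikes <- config$spike_mirnas
        isSpike <- if (!is.null(spikes) && nrow(spikes) > 0)
            runif(length(idx)) < config$spike_fraction else
            rep(FALSE, length(idx))
        ins <- character(length(idx))
        if (any(isSpike)) {
            pick <- sample(nrow(spikes), sum(isSpike), replace = TRUE,
                           prob = spikes$abundance)
            ins[isSpike] <- spikes$seq[pick]
            src[idx[isSpike]] <- spikes$name[pick]
        }
        nb <- sum(!isSpike)
        ins[!isSpike] <- .safeBackgroundInserts(
            nb, lens[!isSpike], config$first_base_u_fraction, a3, a5)
        seqs[idx] <- pad(paste0(ins, a3), length(idx))
    }

    idx <- which(cats == "adapter3_null")
    if (length(idx)) {
        out <- .randSeq(length(idx), rep(rl, length(idx)))
        repeat {
            seed3 <- substr(a3, 1, 8)
            bad <- rep(FALSE, length(out))
            for (s in seq_len(rl - 7L)) {
                mm <- .prefixMismatches(out, seed3, from = s)
                bad <- bad | (!is.na(mm) & mm <= 1L)
            }
            if (!any(bad)) break
            out[bad] <- .randSeq(sum(bad), rep(rl, sum(bad)))
        }
        seqs[idx] <- out
    }

    idx <- which(cats == "insert_null")
    if (length(idx)) seqs[idx] <- pad(rep(a3, length(idx)), length(idx))

    idx <- which(cats == "adapter5_contam")
    if (length(idx)) {
        lens <- sample(18:30, length(idx), replace = TRUE)
        tail5 <- .randSeq(length(idx), lens - 8L)
        seqs[idx] <- pad(paste0(substr(a5, 1, 8), tail5, a3), length(idx))
    }

    idx <- which(cats == "polyA")
    if (length(idx)) {
        lens <- sample(18:30, length(idx), replace = TRUE)
        ins <- vapply(lens, function(l) {
            repeat {
                s <- sample(c("A", "C", "G", "T"), l, replace = TRUE,
                            prob = c(0.97, 0.01, 0.01, 0.01))
                if (mean(s == "A") >= 0.9) break
            }
            paste(s, collapse = "")
        }, character(1))
        seqs[idx] <- pad(paste0(ins, a3), length(idx))
    }

    idx <- which(cats == "short_lt18")
    if (length(idx)) {
        lens <- sample(15:17, length(idx), replace = TRUE)
        ins <- .safeBackgroundInserts(length(idx), lens,
                                      config$first_base_u_fraction, a3, a5)
        seqs[idx] <- pad(paste0(ins, a3), length(idx))
    }

    ids <- sprintf("sr%06d", seq_len(n))
    reads <- data.frame(id = ids, seq = seqs,
                        qual = strrep("I", rl),
                        stringsAsFactors = FALSE)
    truthTab <- data.frame(id = ids, category = cats, source = src,
                           stringsAsFactors = FALSE)
    if (!is.null(fastq)) {
        con <- file(fastq, open = "wb")
        writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n",
                          reads$qual), con, sep = "\n")
        close(con)
    }
    if (!is.null(truth))
        write.table(truthTab, truth, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    list(reads = reads, truth = truthTab, fastq = fastq,
         truth_path = truth)
}

#' Generate a genome with planted stem-loop miRNA precursors
#'
#' Each precursor is a (near-)perfect inverted repeat: a random 5' arm, a
#' loop of at least 3 nt, and a 3' arm derived from the reverse complement
#' of the 5' arm with an optional number of substitutions placed outside
#' the mature/star duplex.  A 21-nt mature miRNA is embedded in one arm
#' (chosen at random) such that its star partner, under the 2-nt 3'
#' overhang convention, lies fully within the other arm.  Total precursor
#' length is drawn from 100-400 nt.  Precursors are placed on random
#' strands at non-overlapping loci.
#'
#' @param n_precursors number of precursors to plant
#' @param genome_length length of the single synthetic chromosome
#' @param seed integer seed
#' @param mature_len mature miRNA length (default 21)
#' @param star_mutations substitutions applied to the 3' arm outside the
#'   mature/star duplex (default 2; 0 gives a perfect inverted repeat)
#' @param fasta,gff optional output paths (FASTA genome, GFF3 truth)
#' @return list with \code{genome} (named \link[Biostrings]{DNAStringSet})
#'   and \code{truth} (\link[GenomicRanges]{GRanges} with columns
#'   \code{ID}, \code{type} in precursor/mature/star/loop, \code{arm})
#' @export
generateGenomeWithPrecursors <- function(n_precursors, genome_length = 50000L,
                                         seed = 1L, mature_len = 21L,
                                         star_mutations = 2L,
                                         fasta = NULL, gff = NULL) {
    set.seed(seed)
    chrom <- "chr1"
    bg <- strsplit(.randSeq(1L, genome_length), "")[[1]]

    recs <- list()
    if (n_precursors > 0) {
        loopLen <- sample(8:20, n_precursors, replace = TRUE)
        total <- sample(100:400, n_precursors, replace = TRUE)
        stem <- (total - loopLen) %/% 2L
        total <- 2L * stem + loopLen
        leftover <- genome_length - sum(total) - 20L * n_precursors
        if (leftover < n_precursors + 1L)
            stop("impossible packing: genome_length too small for ",
                 n_precursors, " precursors")
        cuts <- sort(sample.int(leftover, n_precursors))
        gaps <- diff(c(0L, cuts))
        starts <- integer(n_precursors)
        cursor <- 1L
        for (i in seq_len(n_precursors)) {
            cursor <- cursor + gaps[i] + 10L
            starts[i] <- cursor
            cursor <- cursor + total[i] + 10L
        }

        for (i in seq_len(n_precursors)) {
            S <- stem[i]; L <- loopLen[i]; T <- total[i]
            arm5 <- strsplit(.randSeq(1L, S), "")[[1]]
            loop <- strsplit(.randSeq(1L, L), "")[[1]]
            arm3 <- rev(unname(.COMP[arm5]))
            arm <- sample(c("5p", "3p"), 1L)
            if (arm == "5p") {
                m1 <- sample(3:(S - mature_len + 1L), 1L)
            } else {
                m1 <- sample((S + L + 3L):(T - mature_len - 1L), 1L)
            }
            m2 <- m1 + mature_len - 1L
            s1 <- T - m2 + 3L; s2 <- T - m1 + 3L  # star, 2-nt 3' overhang
            pre <- c(arm5, loop, arm3)
            if (star_mutations > 0L) {
                protected <- c(max(1L, m1 - 2L):min(T, m2 + 2L),
                               max(1L, s1 - 2L):min(T, s2 + 2L),
                               (T - m2):(T - m1 + 2L),  # mature partners
                               (T - s2):(T - s1 + 2L))  # star partners
                pool <- setdiff((S + L + 1L):T, protected)
                if (length(pool) >= star_mutations) {
                    mut <- sample(pool, star_mutations)
                    for (p in mut)
                        pre[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                 pre[p]), 1L)
                }
            }
            strandI <- sample(c("+", "-"), 1L)
            gstart <- starts[i]
            ins <- if (strandI == "+") pre else
                rev(unname(.COMP[pre]))
            bg[gstart:(gstart + T - 1L)] <- ins
            loc <- function(a, b) {  # local [a,b] -> genomic interval
                if (strandI == "+")
                    c(gstart + a - 1L, gstart + b - 1L)
                else c(gstart + T - b, gstart + T - a)
            }
            id <- sprintf("plant%02d", i)
            for (feat in list(
                list(type = "precursor", iv = loc(1L, T)),
                list(type = "mature", iv = loc(m1, m2)),
                list(type = "star", iv = loc(s1, s2)),
                list(type = "loop", iv = loc(S + 1L, S + L)))) {
                recs[[length(recs) + 1L]] <-
                    data.frame(start = feat$iv[1], end = feat$iv[2],
                               strand = strandI, type = feat$type,
                               ID = id, arm = arm,
                               stringsAsFactors = FALSE)
            }
        }
    }

    genome <- DNAStringSet(setNames(paste(bg, collapse = ""), chrom))
    truth <- if (length(recs)) {
        df <- do.call(rbind, recs)
        gr <- GRanges(chrom, IRanges(df$start, df$end), strand = df$strand)
        mcols(gr)$type <- df$type
        mcols(gr)$ID <- df$ID
        mcols(gr)$arm <- df$arm
        gr
    } else GRanges()
    if (!is.null(fasta)) writeXStringSet(genome, fasta)
    if (!is.null(gff)) rtracklayer::export(truth, gff, format = "gff3")
    list(genome = genome, truth = truth)
}

#' Build a tag set from planted precursor truth plus background tags
#'
#' Extracts the mature sequence of every planted precursor (strand-aware),
#' assigns it a read count, and adds non-genomic background tags, giving a
#' ready-made input for \code{\link{callNovelMirnas}} recovery benchmarks.
#'
#' @param genome,truth output of \code{\link{generateGenomeWithPrecursors}}
#' @param count_range integer range of mature read counts
#' @param n_background number of random background tags (count 1-5)
#' @param seed integer seed
#' @return a \linkS4class{TagSet}
#' @export
simulatePrecursorTags <- function(genome, truth, count_range = c(50L, 500L),
                                  n_background = 50L, seed = 1L) {
    set.seed(seed)
    mat <- truth[mcols(truth)$type == "mature"]
    seqs <- character(0); counts <- integer(0)
    if (length(mat)) {
        seqs <- vapply(seq_along(mat), function(i) {
            s <- subseq(genome[[as.character(seqnames(mat))[i]]],
                        start(mat)[i], end(mat)[i])
            if (as.character(strand(mat))[i] == "-")
                s <- reverseComplement(s)
            as.character(s)
        }, character(1))
        counts <- sample(count_range[1]:count_range[2], length(mat),
                         replace = TRUE)
    }
    if (n_background > 0) {
        bg <- .randSeq(n_background, sample(20:24, n_background,
                                            replace = TRUE))
        bg <- setdiff(unique(bg), seqs)
        seqs <- c(seqs, bg)
        counts <- c(counts, sample(1:5, length(bg), replace = TRUE))
    }
    tagSet(seqs, counts)
}

#' Generate a synthetic stem-loop RT-qPCR Ct table
#'
#' For each miRNA and tissue in the design, target Ct values are
#' \code{base_ct - log2(fold)} plus Gaussian noise, and the reference gene
#' has constant \code{ref_ct} plus noise, per replicate.  With
#' \code{noise_sd = 0}, \code{\link{deltaDeltaCt}} returns exactly the
#' designed fold changes (relative to the calibrator tissue, whose design
#' fold should be 1).
#'
#' @param design data.frame with columns \code{mirna}, \code{tissue},
#'   \code{fold} (true fold change vs the calibrator tissue)
#' @param n_reps biological replicates per condition (>= 1)
#' @param noise_sd Gaussian Ct noise, in cycles (>= 0)
#' @param seed integer seed
#' @param reference_gene name of the reference gene rows
#' @param base_ct,ref_ct baseline Ct of targets and the reference
#' @return data.frame with columns gene, tissue, replicate, ct
#' @export
generateCtTable <- function(design, n_reps = 3L, noise_sd = 0, seed = 1L,
                            reference_gene = "rRNA5.8S",
                            base_ct = 24, ref_ct = 18) {
    stopifnot(is.data.frame(design),
              all(c("mirna", "tissue", "fold") %in% colnames(design)))
    if (n_reps < 1) stop("n_reps must be >= 1")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    set.seed(seed)
    rows <- list()
    tissues <- unique(design$tissue)
    for (ti in tissues) {
        for (r in seq_len(n_reps)) {
            rows[[length(rows) + 1L]] <- data.frame(
                gene = reference_gene, tissue = ti, replicate = r,
                ct = ref_ct + rnorm(1, 0, noise_sd),
                stringsAsFactors = FALSE)
        }
    }
    for (i in seq_len(nrow(design))) {
        for (r in seq_len(n_reps)) {
            rows[[length(rows) + 1L]] <- data.frame(
                gene = design$mirna[i], tissue = design$tissue[i],
                replicate = r,
                ct = base_ct - log2(design$fold[i]) +
                    rnorm(1, 0, noise_sd),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    if (any(out$ct <= 0)) stop("generated Ct <= 0; lower noise_sd")
    out
}
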