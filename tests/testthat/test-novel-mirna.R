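test_that("exact mapping finds planted tags on both strands with truth coordinates", {
    set.seed(61)
    bg <- randomDna(3000)
    tagP <- randomDna(21)
    tagM <- randomDna(21)
    rcM <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tagM)))
    g <- paste0(substr(bg, 1, 500), tagP, substr(bg, 522, 1500),
                rcM, substr(bg, 1522, 3000))
    genome <- Biostrings::DNAStringSet(c(chr1 = g))
    ts <- tagSet(c(tagP, tagM, randomDna(22)), c(10L, 5L, 1L))
    hits <- mapTags(ts, genome)
    hp <- hits[hits$tag == tagP, ]
    expect_equal(nrow(hp), 1)
    expect_equal(hp$start, 501); expect_equal(hp$end, 521)
    expect_equal(hp$strand, "+")
    hm <- hits[hits$tag == tagM, ]
    expect_equal(hm$strand, "-")
    expect_equal(substr(g, hm$start, hm$end), rcM)
    ## absent tag -> no loci
    expect_equal(sum(hits$tag == as.character(tagSequences(ts))[3]), 0)
})

test_that("block clustering matches a quadratic brute-force oracle", {
    h2 <- data.frame(tag = c("A", "B"), count = c(1, 1),
                     chrom = "chr1", start = c(100, 150),
                     end = c(120, 170), strand = "+", n_hits = 1)
    expect_equal(nrow(clusterBlocks(h2, 200)$blocks), 1)
    h2$start[2] <- 450; h2$end[2] <- 470   # 330 nt gap > 200
    expect_equal(nrow(clusterBlocks(h2, 200)$blocks), 2)

    bruteCluster <- function(hits, max_gap) {
        n <- nrow(hits)
        adj <- matrix(FALSE, n, n)
        for (i in seq_len(n)) for (j in seq_len(n)) {
            sameTrack <- hits$chrom[i] == hits$chrom[j] &&
                hits$strand[i] == hits$strand[j]
            gap <- max(hits$start[i], hits$start[j]) -
                min(hits$end[i], hits$end[j])
            adj[i, j] <- sameTrack && gap <= max_gap
        }
        comp <- seq_len(n)
        repeat {
            changed <- FALSE
            for (i in seq_len(n)) for (j in seq_len(n))
                if (adj[i, j] && comp[j] > comp[i]) {
                    comp[comp == comp[j]] <- comp[i]; changed <- TRUE
                }
            if (!changed) break
        }
        comp
    }
    set.seed(71)
    for (rep in 1:5) {
        n <- 25
        hits <- data.frame(
            tag = sprintf("t%02d", 1:n), count = sample(1:9, n, TRUE),
            chrom = sample(c("c1", "c2"), n, TRUE),
            start = sample(1:3000, n), strand = sample(c("+", "-"), n, TRUE),
            n_hits = 1, stringsAsFactors = FALSE)
        hits$end <- hits$start + 20
        got <- clusterBlocks(hits, 150)
        comp <- bruteCluster(got$members, 150)
        ## same partition: block ids refine identically
        expect_equal(length(unique(comp)), nrow(got$blocks))
        expect_true(all(tapply(comp, got$members$block_id,
                               function(x) length(unique(x))) == 1))
    }
})

test_that("planted precursors are accepted with the correct arm and star", {
    gg <- generateGenomeWithPrecursors(4, 25000, seed = 81,
                                       star_mutations = 0)
    tags <- simulatePrecursorTags(gg$genome, gg$truth, n_background = 0,
                                  seed = 82)
    hits <- mapTags(tags, gg$genome)
    cl <- clusterBlocks(hits)
    mat <- gg$truth[S4Vectors::mcols(gg$truth)$type == "mature"]
    star <- gg$truth[S4Vectors::mcols(gg$truth)$type == "star"]
    accepted <- 0
    for (i in seq_len(nrow(cl$blocks))) {
        cand <- evaluatePrecursor(cl$blocks[i, , drop = FALSE],
                                  cl$members, gg$genome)
        if (!cand@accepted) next
        accepted <- accepted + 1
        ## the call's window overlaps a planted locus on some strand;
        ## when the called strand matches the planted strand, the arm and
        ## star sequence must match the plant
        ov <- which(GenomicRanges::start(mat) <= cand@windowEnd &
                    GenomicRanges::end(mat) >= cand@windowStart)
        expect_true(length(ov) >= 1)
        j <- ov[1]
        if (as.character(GenomicRanges::strand(mat))[j] == cand@strand) {
            expect_equal(cand@arm, S4Vectors::mcols(mat)$arm[j])
            sseq <- as.character(Biostrings::subseq(
                gg$genome[[1]], GenomicRanges::start(star)[j],
                GenomicRanges::end(star)[j]))
            if (cand@strand == "-")
                sseq <- as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(sseq)))
            expect_equal(cand@star, sseq)
        }
    }
    expect_gte(accepted, 4)  # each plant is hit on >= 1 strand
})

test_that("an unstructured (shuffled) window is rejected by the duplex criteria", {
    set.seed(91)
    mature <- randomDna(21)
    repeat {  # shuffled context: no star partner anywhere near the tag
        ctx <- paste(sample(strsplit(randomDna(400), "")[[1]]),
                     collapse = "")
        if (!grepl(mature, ctx, fixed = TRUE)) break
    }
    g <- paste0(substr(ctx, 1, 200), mature, substr(ctx, 222, 400))
    genome <- Biostrings::DNAStringSet(c(chr1 = g))
    ts <- tagSet(mature, 50L)
    cl <- clusterBlocks(mapTags(ts, genome))
    cand <- evaluatePrecursor(cl$blocks[1, , drop = FALSE], cl$members,
                              genome)
    expect_false(cand@accepted)
    ## the mature/star duplex criteria are what fails on random context
    v <- cand@verdicts
    expect_false(all(v[c("mature_paired", "star_contiguous",
                         "loop_excludes_mature", "duplex_energy")]))
})

test_that("a mature overlapping the loop fails loop_excludes_mature", {
    ## hairpin whose mature candidate straddles the loop: the tag is a
    ## self-complementary segment centred on the loop
    arm <- randomDna(60)
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(arm)))
    hp <- paste0(arm, "AAAA", rc)
    tag <- substr(hp, 52, 72)  # spans arm end, loop, rc start
    pad1 <- randomDna(100); pad2 <- randomDna(100)
    genome <- Biostrings::DNAStringSet(c(chr1 = paste0(pad1, hp, pad2)))
    ts <- tagSet(tag, 30L)
    cl <- clusterBlocks(mapTags(ts, genome))
    cand <- evaluatePrecursor(cl$blocks[1, , drop = FALSE], cl$members,
                              genome)
    expect_false(cand@accepted)
    expect_false(cand@verdicts[["loop_excludes_mature"]])
})

test_that("novel calling recovers planted loci and stays silent elsewhere", {
    gg <- generateGenomeWithPrecursors(10, 60000, seed = 11)
    tags <- simulatePrecursorTags(gg$genome, gg$truth, seed = 12)
    nov <- callNovelMirnas(tags, gg$genome)
    pre <- gg$truth[S4Vectors::mcols(gg$truth)$type == "precursor"]
    calls <- GenomicRanges::GRanges(
        nov$calls$chrom, IRanges::IRanges(nov$calls$start, nov$calls$end))
    recovered <- sum(GenomicRanges::countOverlaps(pre, calls) > 0)
    expect_gte(recovered, 9)
    ## exactly one arm column populated, mature maps inside its window
    expect_true(all(xor(nov$calls$seq_5p != "-", nov$calls$seq_3p != "-")))
    for (i in seq_len(nrow(nov$calls))) {
        m <- if (nov$calls$seq_5p[i] != "-") nov$calls$seq_5p[i] else
            nov$calls$seq_3p[i]
        win <- as.character(Biostrings::subseq(
            gg$genome[[1]], nov$calls$start[i], nov$calls$end[i]))
        if (nov$calls$strand[i] == "-")
            win <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(win)))
        expect_true(grepl(m, win, fixed = TRUE))
    }
    ## precursor-free genome of equal length: zero calls
    g0 <- generateGenomeWithPrecursors(0, 60000, seed = 13)
    expect_equal(nrow(callNovelMirnas(tags, g0$genome)$calls), 0)
})

test_that("acceptance is monotone in the energy threshold", {
    gg <- generateGenomeWithPrecursors(3, 20000, seed = 33)
    tags <- simulatePrecursorTags(gg$genome, gg$truth, n_background = 10,
                                  seed = 34)
    strict <- callNovelMirnas(tags, gg$genome,
                              thresholds = precursorThresholds(
                                  mfe_max = -60))
    loose <- callNovelMirnas(tags, gg$genome,
                             thresholds = precursorThresholds(
                                 mfe_max = -20))
    ## every locus called under the stricter energy threshold is still
    ## called (as an overlapping window) under the looser one
    if (nrow(strict$calls) > 0) {
        gs <- GenomicRanges::GRanges(strict$calls$chrom,
                                     IRanges::IRanges(strict$calls$start,
                                                      strict$calls$end))
        gl <- GenomicRanges::GRanges(loose$calls$chrom,
                                     IRanges::IRanges(loose$calls$start,
                                                      loose$calls$end))
        expect_true(all(GenomicRanges::countOverlaps(gs, gl) > 0))
    }
    expect_gte(nrow(loose$calls), nrow(strict$calls))
})
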