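# shared fixture builders; everything is generated in code at test time

# small random genotype matrix with prescribed column MAFs
makeGenotypes <- function(n, maf, seed = 1) {
    withr::with_seed(seed, {
        d <- vapply(maf, function(f) stats::rbinom(n, 2, f), numeric(n))
        RegionGenotypes(d, paste0("v", seq_along(maf)))
    })
}

# haplotype pair set drawn from given identifier frequencies
makePairs <- function(n, freq, seed = 1) {
    withr::with_seed(seed, {
        ids <- sample(names(freq), 2 * n, replace = TRUE, prob = freq)
        HaplotypePairSet(matrix(ids, ncol = 2))
    })
}

# a small simulated case-control replicate (shared by several files)
makeReplicate <- function(seed = 101, scenario = "Common",
                          basis = "genotype", n = 200) {
    pool <- generatePool(20, 4000, seed = seed)
    model <- selectCausal(pool, basis, scenario, 0.5, seed = seed + 1)
    sampleCaseControl(pool, model, n / 2, n / 2, seed = seed + 2)
}

# write a tiny VCF from explicit GT strings (sites x samples)
writeToyVcf <- function(gt, path, chrom = "1", pos = NULL,
                        ref = "A", alt = "G") {
    L <- nrow(gt)
    if (is.null(pos)) pos <- seq(100, by = 10, length.out = L)
    samples <- paste0("S", seq_len(ncol(gt)))
    lines <- c("##fileformat=VCFv4.2",
               paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                      "Description=\"Genotype\">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"))
    for (j in seq_len(L))
        lines <- c(lines, paste(c(chrom, pos[j], paste0("snp", j), ref,
                                  alt, ".", "PASS", ".", "GT", gt[j, ]),
                                collapse = "\t"))
    writeLines(lines, path)
    path
}

# cached scaled null study used by the acceptance checks (computed once
# per test run: 1000 replicates of 500 cases / 500 controls, 200
# permutations each, pools of 40000 chromosomes shared by 5 replicates)
.nullStudyCache <- new.env(parent = emptyenv())
nullStudyCached <- function() {
    if (is.null(.nullStudyCache$res)) {
        scen <- data.frame(basis = "genotype", scenario = "null")
        .nullStudyCache$res <- runPowerStudy(
            scen, nReplicates = 1000L, nPermutations = 200L,
            replicatesPerPool = 5L, seed = 20130821L)
    }
    .nullStudyCache$res
}
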