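# Shared desk-scale fixtures, built in code.

# 4 chromosomes of 1 Mb, centromere at 400 kb, capture = 1-kb tiles every
# 5 kb (200 kb captured per chromosome). Small enough for base-level oracles.
mini_genome <- function() {
  toy_genome(n_chrom = 4, chrom_length = 1e6, centromere = 4e5,
             tile_width = 1000, tile_spacing = 5000)
}

make_variants <- function(n, seed = 1, sample = "S1", genome = toy_genome()) {
  set.seed(seed)
  cap <- genome$capture
  tile <- cap[sample.int(nrow(cap), n, replace = TRUE), ]
  pos <- tile$start + floor(runif(n) * (tile$end - tile$start + 1))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                "")
  data.frame(sample = sample, chrom = tile$chrom, pos = pos, ref = ref,
             alt = alt,
             variant_class = sample(c("Missense_Mutation", "Silent",
                                      "Nonsense_Mutation", "3'UTR"),
                                    n, replace = TRUE),
             vaf = round(runif(n, 0, 0.9), 4),
             t_depth = sample(5:300, n, replace = TRUE),
             n_depth = sample(5:200, n, replace = TRUE),
             gene = paste0("G", sample.int(50, n, replace = TRUE)),
             variant_type = "SNV")
}

make_segments <- function(sample, chrom, start, end, tn_ratio) {
  data.frame(sample = sample, chrom = as.character(chrom), start = start,
             end = end, tn_ratio = tn_ratio, log2_ratio = log2(tn_ratio))
}

# whole-genome neutral segmentation for one sample
flat_segments <- function(genome, sample = "S1", tn_ratio = 1.0) {
  do.call(rbind, lapply(genome$chrom_names, function(ch)
    make_segments(sample, ch, 1, genome$chrom_lengths[[ch]], tn_ratio)))
}
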