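# Handcrafted 120-bp genome with one gene per strand, used as the oracle
# for effect classification.  Layout (1-based, inclusive):
#
#   plus-strand gene gp:
#     5'UTR 11-16, exon1 11-28 (CDS 17-28), intron 29-40,
#     exon2 41-58 (CDS 41-52, 3'UTR 53-58)
#     CDS codons: ATG TTT CAA GAT | CCC GGG TAC TAA
#       genomic 17-19 ATG, 20-22 TTT, 23-25 CAA, 26-28 GAT,
#               41-43 CCC, 44-46 GGG, 47-49 TAC, 50-52 TAA
#   minus-strand gene gm (single exon 70-105):
#     3'UTR 70-75, CDS 76-99, 5'UTR 100-105
#     coding-strand CDS: ATG GCT GCA AGC TTA TCG TTT TGA
#     genomic 76-99 = revcomp = TCAAAACGATAAGCTTGCAGCCAT
#
# Background is poly-T so every untouched position has ref "T".
tiny_genome <- function() {
  s <- rep("T", 120)
  put <- function(pos, str) {
    ch <- strsplit(str, "")[[1]]
    s[pos:(pos + length(ch) - 1)] <<- ch
  }
  put(17, "ATGTTTCAAGAT")          # gp CDS part 1
  put(41, "CCCGGGTACTAA")          # gp CDS part 2
  put(76, "TCAAAACGATAAGCTTGCAGCCAT")  # gm CDS (genomic strand)
  genes <- data.frame(gene_id = c("gp", "gm"), contig = "c1",
                      strand = c("+", "-"))
  features <- rbind(
    data.frame(gene_id = "gp", type = "five_prime_UTR", start = 11, end = 16),
    data.frame(gene_id = "gp", type = "exon", start = 11, end = 28),
    data.frame(gene_id = "gp", type = "CDS", start = 17, end = 28),
    data.frame(gene_id = "gp", type = "exon", start = 41, end = 58),
    data.frame(gene_id = "gp", type = "CDS", start = 41, end = 52),
    data.frame(gene_id = "gp", type = "three_prime_UTR", start = 53, end = 58),
    data.frame(gene_id = "gm", type = "exon", start = 70, end = 105),
    data.frame(gene_id = "gm", type = "three_prime_UTR", start = 70, end = 75),
    data.frame(gene_id = "gm", type = "CDS", start = 76, end = 99),
    data.frame(gene_id = "gm", type = "five_prime_UTR", start = 100, end = 105))
  ma_genome(c(c1 = paste(s, collapse = "")),
            annotation = annotation(genes, features))
}

# candidate set built directly from a spec: one row per candidate with
# per-sample depths; samples default ancestor + L1..L3
make_candidates <- function(df, samples = c("anc", "L1", "L2", "L3"),
                            ancestor = "anc") {
  n <- nrow(df)
  dp <- matrix(30, n, length(samples), dimnames = list(NULL, samples))
  ad <- matrix(0, n, length(samples), dimnames = list(NULL, samples))
  for (i in seq_len(n)) {
    dp[i, df$line[i]] <- df$dp[i]
    ad[i, df$line[i]] <- df$ad[i]
    if (!is.null(df$anc_ad) && df$anc_ad[i] > 0) ad[i, ancestor] <- df$anc_ad[i]
    if (!is.null(df$other_ad) && df$other_ad[i] > 0) {
      other <- setdiff(samples, c(ancestor, df$line[i]))[1]
      ad[i, other] <- df$other_ad[i]
    }
  }
  sites <- data.frame(contig = "c1", pos = df$pos, ref = df$ref,
                      alt = df$alt,
                      mq = if (is.null(df$mq)) 60 else df$mq,
                      indel_dist = if (is.null(df$indel_dist)) Inf
                                   else df$indel_dist)
  ma_candidates(sites, dp, ad, ancestor)
}

# CDS string from codon vector
codon_cds <- function(...) paste(c("ATG", ..., "TAA"), collapse = "")
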