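# Shared fixture builders; every fixture is generated in code.

random_count_table <- function(n_samples, n_otus, lambda = 5, seed = NULL,
                               sample_prefix = "samp", otu_prefix = "OTU") {
  build <- function() {
    m <- matrix(rpois(n_samples * n_otus, lambda), nrow = n_samples,
                dimnames = list(paste0(sample_prefix, seq_len(n_samples)),
                                paste0(otu_prefix, seq_len(n_otus))))
    count_table(m)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# Count table of technical replicate libraries of one source sample.
replicate_table <- function(counts_list, source = "SRC", platform = "illumina") {
  ids <- paste0("rep", seq_along(counts_list))
  n_otus <- length(counts_list[[1]])
  m <- do.call(rbind, counts_list)
  dimnames(m) <- list(ids, paste0("OTU", seq_len(n_otus)))
  meta <- data.frame(sample_id = ids, source_id = source, pool_size = 1L,
                     platform = platform, group = "site1",
                     replicate_index = seq_along(ids))
  count_table(m, meta)
}

community_profile_for_test <- function(ab,
                                       ids = paste0("OTU", seq_along(ab))) {
  ampliconrep:::community_profile(ids, ab)
}

small_sim_config <- function(seed = 1, ...) {
  args <- list(n_taxa = 60,
               template_molecules = 2000,
               depth_by_platform = list(p454 = c(300, 500),
                                        illumina = c(2000, 3000)),
               rarefy_depth_replication = c(p454 = 300, illumina = 2000),
               rarefy_depth_cross = c(p454 = 300, illumina = 2000),
               samples_per_site = 3,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

expect_same_file <- function(a, b) {
  expect_identical(unname(tools::md5sum(a)), unname(tools::md5sum(b)),
                   label = paste("contents of", basename(a)))
}
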