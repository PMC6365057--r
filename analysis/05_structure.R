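#!/usr/bin/env Rscript
# GPCR chimera structural-compatibility analysis. Always runs on the
# synthetic helix bundle (known ground truth); additionally runs the
# published four-structure benchmark (rhodopsin 1U19/3PQR vs Smoothened
# 4JKV/6D32) when the PDB files are available locally under analysis/pdb/
# (e.g. fetched with bio3d::get.pdb on a networked machine).

library(gastruquant)

dir.create("results", showWarnings = FALSE)

## synthetic bundle: superposition RMSD and contact network
b <- make_helix_bundle(7, 30, spacing = 10, perturbation_sigma = 0.5,
                       transform_copy = TRUE, seed = 5L)
sp <- superpose(b, b$copy, pair_residues(b$annotation, b$annotation))
cat(sprintf("synthetic bundle: RMSD %.3f A over %d CA pairs (truth %.3f A)\n",
            sp$rmsd, sp$n_pairs, b$truth$rmsd))

ring <- make_helix_bundle(7, 25, spacing = 7, seed = 6L)
ic <- interhelical_counts(contact_network(ring))
dist7 <- contact_distribution(ic)
cat(sprintf("contact ring: %d contacts over %d segment pairs\n",
            ic$total, nrow(ic$counts)))
write.csv(merge(ic$counts, dist7$fractions), "results/bundle_contacts.csv",
          row.names = FALSE)

## published benchmark (needs the four PDB files)
pdb_dir <- "analysis/pdb"
ids <- c("1u19", "4jkv", "3pqr", "6d32")
files <- file.path(pdb_dir, paste0(ids, ".pdb"))
if (all(file.exists(files))) {
  annf <- system.file("extdata", "gpcr_tm_segments.yaml",
                      package = "gastruquant")
  cfg <- yaml::read_yaml(annf)
  models <- setNames(lapply(ids, function(id)
    read_structure(file.path(pdb_dir, paste0(id, ".pdb")),
                   chain = cfg[[id]]$chain,
                   exclusions = lapply(cfg[[id]]$exclusions, unlist))), ids)
  anns <- setNames(lapply(ids, function(id) read_annotation(annf, id)), ids)
  tm <- function(a) a[paste0("TM", 1:7)]
  for (pair in list(c("1u19", "4jkv", "inactive"),
                    c("3pqr", "6d32", "active"))) {
    p <- pair_residues(tm(anns[[pair[1]]]), tm(anns[[pair[2]]]))
    s <- superpose(models[[pair[1]]], models[[pair[2]]], p)
    cat(sprintf("%s state: TM RMSD %.2f A over %d pairs\n",
                pair[3], s$rmsd, s$n_pairs))
  }
  adjacent <- c("TM1-TM2", "TM2-TM3", "TM3-TM4", "TM3-TM5", "TM5-TM6",
                "TM6-TM7")
  for (id in ids) {
    net <- contact_network(models[[id]], anns[[id]])
    icx <- interhelical_counts(net)
    dx <- contact_distribution(icx, focus_pairs = adjacent)
    cat(sprintf("%s: %d inter-helical contacts, %.0f%% on adjacent pairs\n",
                id, icx$total, 100 * dx$focus_fraction))
    write.csv(icx$counts,
              sprintf("results/contacts_%s.csv", id), row.names = FALSE)
  }
} else {
  cat("published-benchmark PDB files not found under", pdb_dir,
      "- skipping the four-structure comparison\n")
}
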