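# One-off generator for inst/extdata/pathway_mapping_synthetic.tsv
# Synthetic membership structure at the scale of a 37-metabolite NMR panel
# vs 138 KEGG pathway names, 468 edges total.
metabolites <- c(
  "2-hydroxyglutarate", "Acetate", "Alanine", "Arginine", "Ascorbate",
  "Aspartate", "Betaine", "Choline", "Creatine", "Ethanolamine", "GABA",
  "Glucose", "Glutamate", "Glutamine", "Glutathione",
  "Glycerophosphocholine", "Glycine", "Histidine", "Hypotaurine",
  "Isoleucine", "Lactate", "Leucine", "Lysine", "Methionine",
  "Myo-inositol", "N-acetylaspartate", "Phenylalanine", "Phosphocholine",
  "Phosphocreatine", "Proline", "Scyllo-inositol", "Serine", "Succinate",
  "Taurine", "Threonine", "Tyrosine", "Valine")
stopifnot(length(metabolites) == 37L)

pathways <- c(
  "Glycolysis / Gluconeogenesis", "Citrate cycle (TCA cycle)",
  "Pentose phosphate pathway", "Pentose and glucuronate interconversions",
  "Fructose and mannose metabolism", "Galactose metabolism",
  "Ascorbate and aldarate metabolism", "Fatty acid biosynthesis",
  "Fatty acid elongation", "Fatty acid degradation",
  "Synthesis and degradation of ketone bodies", "Steroid biosynthesis",
  "Primary bile acid biosynthesis", "Steroid hormone biosynthesis",
  "Oxidative phosphorylation", "Purine metabolism", "Pyrimidine metabolism",
  "Alanine, aspartate and glutamate metabolism",
  "Glycine, serine and threonine metabolism",
  "Cysteine and methionine metabolism",
  "Valine, leucine and isoleucine degradation",
  "Valine, leucine and isoleucine biosynthesis", "Lysine biosynthesis",
  "Lysine degradation", "Arginine biosynthesis",
  "Arginine and proline metabolism", "Histidine metabolism",
  "Tyrosine metabolism", "Phenylalanine metabolism", "Tryptophan metabolism",
  "Phenylalanine, tyrosine and tryptophan biosynthesis",
  "beta-Alanine metabolism", "Taurine and hypotaurine metabolism",
  "Phosphonate and phosphinate metabolism", "Selenocompound metabolism",
  "D-Amino acid metabolism", "Glutathione metabolism",
  "Starch and sucrose metabolism",
  "Amino sugar and nucleotide sugar metabolism",
  "Glycosaminoglycan biosynthesis", "Glycerolipid metabolism",
  "Inositol phosphate metabolism", "Glycerophospholipid metabolism",
  "Ether lipid metabolism", "Arachidonic acid metabolism",
  "Linoleic acid metabolism", "alpha-Linolenic acid metabolism",
  "Sphingolipid metabolism", "Pyruvate metabolism",
  "Glyoxylate and dicarboxylate metabolism", "Propanoate metabolism",
  "Butanoate metabolism", "C5-Branched dibasic acid metabolism",
  "One carbon pool by folate", "Methane metabolism", "Thiamine metabolism",
  "Riboflavin metabolism", "Vitamin B6 metabolism",
  "Nicotinate and nicotinamide metabolism",
  "Pantothenate and CoA biosynthesis", "Biotin metabolism",
  "Lipoic acid metabolism", "Folate biosynthesis", "Retinol metabolism",
  "Porphyrin metabolism", "Terpenoid backbone biosynthesis",
  "Nitrogen metabolism", "Sulfur metabolism", "Aminoacyl-tRNA biosynthesis",
  "Metabolism of xenobiotics by cytochrome P450",
  "Drug metabolism - cytochrome P450", "Drug metabolism - other enzymes",
  "Biosynthesis of unsaturated fatty acids", "Biosynthesis of amino acids",
  "Carbon metabolism", "2-Oxocarboxylic acid metabolism",
  "Fatty acid metabolism", "Degradation of aromatic compounds",
  "Nucleotide metabolism", "ABC transporters",
  "Neuroactive ligand-receptor interaction", "cAMP signaling pathway",
  "cGMP-PKG signaling pathway", "mTOR signaling pathway",
  "AMPK signaling pathway", "PI3K-Akt signaling pathway",
  "HIF-1 signaling pathway", "FoxO signaling pathway",
  "Calcium signaling pathway", "Phosphatidylinositol signaling system",
  "Sphingolipid signaling pathway", "Glucagon signaling pathway",
  "Insulin signaling pathway", "Insulin secretion",
  "Oxytocin signaling pathway", "GnRH signaling pathway",
  "Prolactin signaling pathway", "Thyroid hormone synthesis",
  "Adipocytokine signaling pathway", "Synaptic vesicle cycle",
  "Glutamatergic synapse", "GABAergic synapse", "Cholinergic synapse",
  "Serotonergic synapse", "Dopaminergic synapse", "Long-term potentiation",
  "Long-term depression", "Retrograde endocannabinoid signaling",
  "Taste transduction", "Olfactory transduction", "Phototransduction",
  "Regulation of actin cytoskeleton", "Gap junction", "Tight junction",
  "Ferroptosis", "Autophagy - animal", "Mitophagy - animal", "Apoptosis",
  "Necroptosis", "Cellular senescence", "Protein digestion and absorption",
  "Carbohydrate digestion and absorption", "Fat digestion and absorption",
  "Vitamin digestion and absorption", "Mineral absorption",
  "Bile secretion", "Gastric acid secretion", "Pancreatic secretion",
  "Salivary secretion", "Proximal tubule bicarbonate reclamation",
  "Collecting duct acid secretion",
  "Vasopressin-regulated water reabsorption",
  "Aldosterone-regulated sodium reabsorption",
  "Endocrine and other factor-regulated calcium reabsorption",
  "Central carbon metabolism in cancer", "Choline metabolism in cancer",
  "Glioma", "Chemical carcinogenesis - reactive oxygen species")
stopifnot(length(pathways) == 138L)

# hub metabolites participate in many pathways
hubs <- c("Glutamate", "Glutamine", "Glycine", "Alanine", "Aspartate",
          "Glucose", "Serine", "Succinate", "Glutathione", "Choline")
w <- ifelse(metabolites %in% hubs, 4, 1)
cellw <- rep(w, times = 138L)  # column-major over (metabolite, pathway)

set.seed(20260926)
repeat {
  # one member per pathway first, then weighted fill to 468 edges
  base <- cbind(sample.int(37L, 138L, replace = TRUE, prob = w), seq_len(138L))
  base_idx <- (base[, 2L] - 1L) * 37L + base[, 1L]
  rest <- setdiff(seq_len(37L * 138L), base_idx)
  idx <- c(base_idx, sample(rest, 468L - length(base_idx), prob = cellw[rest]))
  m <- ((idx - 1L) %% 37L) + 1L
  q <- ((idx - 1L) %/% 37L) + 1L
  if (length(unique(m)) == 37L) break  # every metabolite mapped at least once
}
edges <- data.frame(metabolite = metabolites[m], pathway = pathways[q])
edges <- edges[order(match(edges$metabolite, metabolites), edges$pathway), ]
stopifnot(nrow(unique(edges)) == 468L)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.table(edges, "inst/extdata/pathway_mapping_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
cat("edges:", nrow(edges), " pathways:", length(unique(edges$pathway)), "\n")
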