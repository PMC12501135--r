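#!/usr/bin/env Rscript
# Session-level nonparametric statistics: Kruskal-Wallis across cognitive
# loads for the EIB AUC and the CAP1 persistence points, with Dunn-style
# post hoc mean-rank differences (FDR corrected).

suppressPackageStartupMessages(library(eibdyn))

conditions <- c("rest", "0back", "1back", "2back")

kin <- read.delim("results/kinetics.tsv")
aucs <- unique(kin[, c("subject", "session", "auc")])
kw_auc <- kruskal_wallis_mrd(split(aucs$auc,
                                   factor(aucs$session, levels = conditions)))
cat("Load effect on normalized-EIB AUC:\n")
print(kw_auc)

pers <- read.delim("results/cap_persistence.tsv")
kw_pers <- kruskal_wallis_mrd(split(pers$persistence,
                                    factor(pers$session,
                                           levels = conditions)))
cat("\nLoad effect on CAP1 persistence points:\n")
print(kw_pers)

out <- list(
  eib_auc = list(statistic = kw_auc$statistic, df = kw_auc$df, n = kw_auc$n,
                 p = kw_auc$p, posthoc = kw_auc$posthoc),
  cap1_persistence = list(statistic = kw_pers$statistic, df = kw_pers$df,
                          n = kw_pers$n, p = kw_pers$p,
                          posthoc = kw_pers$posthoc))
jsonlite::write_json(out, "results/stats.json", auto_unbox = TRUE,
                     digits = NA, dataframe = "rows")
cat("\nStatistics -> results/stats.json\n")
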