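#!/usr/bin/env Rscript
# Visibility-graph temporal features of each normalized EIB curve: the mean
# out-degree of the time-directed natural visibility graph (surrogate for
# the temporal gradient) and the in/out-degree KLD (irreversibility /
# non-stationarity proxy).

suppressPackageStartupMessages(library(eibdyn))

kin <- read.delim("results/kinetics.tsv")
keys <- unique(kin[, c("subject", "session")])
rows <- lapply(seq_len(nrow(keys)), function(i) {
  cur <- kin[kin$subject == keys$subject[i] & kin$session == keys$session[i], ]
  f <- visibility_features(cur$eib_norm[order(cur$frame)])
  data.frame(subject = keys$subject[i], session = keys$session[i],
             feature = c("mean_out_degree", "kld"),
             value = c(f$mean_out_degree, f$kld))
})
tab <- do.call(rbind, rows)
write.table(tab, "results/visgraph.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

od <- tab[tab$feature == "mean_out_degree", ]
kw <- kruskal_wallis_mrd(split(od$value, od$session))
cat("Visibility features -> results/visgraph.tsv\n")
cat("Load effect on EIB mean out-degree:\n")
print(kw)
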