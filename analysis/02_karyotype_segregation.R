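#!/usr/bin/env Rscript
# Goodness of fit of the karyotyped W22/B73 selfed-tetraploid progeny to the
# tetrasomic expectation.
#
# Finds: the 92 tallied chromosome sets (6, 20, 41, 23, 2 across classes
# 4:0 .. 0:4) do not deviate significantly from 1:8:18:8:1 — chi-square 5.63
# on 4 df, p = 0.23 (unrounded expected counts), corroborated by a seeded
# Monte-Carlo multinomial p-value that sidesteps the small expected counts
# (~2.6) in the extreme classes.  Tetrasomic segregation is not rejected.

library(polyself)

dir.create("results", showWarnings = FALSE)

tally <- read_karyotype_table(system.file("extdata",
                                          "karyotype_w22_b73_classes.csv",
                                          package = "polyself"))
print(tally)

gof <- chi_square_gof(tally, expected_class_ratio())
print(gof)

mc <- exact_multinomial_pvalue(tally, expected_class_ratio(),
                               n_sim = 1e5, seed = 20090521)
cat(sprintf("Monte-Carlo multinomial p = %.4f (%s, %d draws)\n",
            mc$p_value, mc$method, mc$n_sim))

write_report(gof, "results/karyotype_gof.json", seed = 20090521,
             overwrite = TRUE)
write_report(data.frame(class = names(tally),
                        observed = as.integer(tally),
                        expected = gof$expected),
             "results/karyotype_expected_counts.csv", overwrite = TRUE)
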