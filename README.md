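# hiermotif

Bayesian decomposition of hierarchical sequence motifs.

## The problem

Some sequence motifs can only be observed through the filter of an upstream
selection step. The canonical example is T cell immunology: a T cell
receptor (TCR) recognizes a peptide only after the peptide has bound an MHC
molecule and been presented on the cell surface, so every immunogenic
peptide also satisfies the MHC binding-and-presentation motif, and the motif
seen in responding peptides is a composite of the two preferences. The TCR's
own preference is hidden inside it.

`hiermotif` is for researchers who have sequences carrying two partially
observed binary binding labels — `w` for the upstream process (e.g. MHC
binding and presentation) and `g` for the downstream one (e.g. T cell
recognition), with `NA` for untested sequences — and want to pull the
composite apart into two distinct position-specific probability matrices
(PSPMs).

## Model and inference

Each sequence `r_i` over a K-letter alphabet carries labels
`w_i, g_i ∈ {0, 1, NA}` and two latent contiguous binding windows of known
lengths J and J̃ with starts `a_i`, `b_i`. Letters in the first window
follow the columns of a K×J matrix Θ, letters in the second follow Θ̃
(K×J̃), everything else follows a background distribution θ₀. Where the
windows overlap — the hierarchical case `w = g = 1` — the second (downstream)
motif dominates: overlapping positions are drawn from Θ̃, and position
`a_i + j − 1` contributes its Θ column j only if it lies outside the second
window.

Inference is MCMC with conjugate Dirichlet priors: Gibbs full-conditional
updates for unknown labels (Bernoulli), binding starts (categorical over
valid starts), and all parameter blocks (`Dirichlet(counts + prior)`),
augmented with two grouped Metropolis-Hastings *shift moves* that translate
all binding starts of one process by ±1 while regenerating the motif matrix
and the unknown labels — the escape hatch for the off-by-one modes that trap
plain motif samplers. Point estimates are maximum a posteriori over the
post-burn-in samples; masked labels are predicted from the MAP state, and
held-out label accuracy drives motif-length selection.

## Worked example

```r
library(hiermotif)

sim <- sim_hier_motifs(seed = 1)   # 200 peptides, planted 9-mer + 5-mer motifs
sim
#> <hm_sim> 200 sequences, K = 20, motif lengths 9 / 5
#>   labels: 60 w = 1, 57 g = 1; masked: 0 w, 148 g

fit <- decompose_motifs(sim$data, first_len = 9, second_len = 5, seed = 2)
fit
#> <hm_fit> 200 sequences, motif lengths 9 / 5, 100 iterations (50 burn-in)
#>   MAP at iteration 73: log-posterior -7386.93, log-likelihood -7005.69

round(attr(recovery_metrics(fit, sim$truth), "map"), 3)
#> error_theta0  error_first error_second        acc_g        acc_a        acc_b
#>        0.004        0.023        0.029        0.878        1.000        1.000
```

The recovery metrics compare the MAP estimate with the generating truth:
the background and both motif matrices are recovered to a few hundredths of
average absolute error per element, 87.8% of the 148 masked `g` labels are
predicted correctly, and every binding start of a truly bound sequence is
located exactly (`acc_a`, `acc_b`).

Tidyverse-style accessors summarise a fit:

```r
glance(fit)        # one-row summary: MAP scores, shift-move acceptance rates
tidy(fit)          # long tibble: motif / position / letter / probability
autoplot(fit)      # log-likelihood and log-posterior traces
plot_motif(fit, "second")
```

Estimated motifs export as plain TSV matrices and MEME minimal format
(`write_motifs(fit, "out/run1")`), ready for logo or scanning tools. Real
data enter through `read_motif_data("peptides.fasta", "labels.tsv")`, and
`scan_second_length()` selects the downstream motif length by masking 20%
of the known `g` labels and maximising held-out prediction accuracy. A
command-line wrapper (`exec/hiermotif`) exposes `simulate`, `fit`,
`predict`, `scan-length` and `evaluate` subcommands.

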