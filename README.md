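# uorfscan

Genome-wide detection, classification, and translation-probability
estimation of upstream open reading frames (uORFs), for researchers
reannotating translation starts in GC-rich genomes — where annotated
5'UTRs are dense in ATGs and the scanning model of initiation says most
annotated CDSs should never be reached.

## What it computes

Every ATG wholly within an annotated, spliced 5'UTR is classified against
the reference CDS start:

| class | definition | consequence if translated |
|---|---|---|
| 1 | in frame, no in-frame stop before the CDS | N-terminal extension of the reference peptide |
| 2 | out of frame, no in-frame stop before the CDS | unrelated peptide read through the CDS start |
| 3 | initiates and terminates within the 5'UTR | short autonomous uORF (reinitiation possible) |

Around this classifier the package implements the full analysis workflow:

- **Transcript assembly** from genome FASTA + GFF3 (spliced 5'UTR / CDS /
  3'UTR, both strands), dORF scanning of 3'UTRs, and ATG frequency tables
  (counts divided by length/3, in and out of frame).
- **Randomized controls**: per-sequence scrambling, dinucleotide-matched
  first-order Markov sequences (plus exact Altschul–Erickson shuffling),
  and partial mutagenesis at r = 0.1/0.2/0.5, with Poisson-SD count tests
  (z = Δ/√(a+b)).
- **Kozak information score**: from n aligned reference-initiator
  contexts, per-position information R_i = 2 − H_i bits and weights
  w_i(n) = R_i p_i(n); a context scores K = Σ_i w_i(b_i) over the −10..+8
  window (ATG excluded).
- **Mixture projection**: the class-1 score (or length) distribution C is
  decomposed as c₁·reference + c₂·random by unconstrained least squares,
  [c₁ c₂] = (AᵀA)⁻¹AᵀC, with proportion of variance explained — the
  estimate of the translated fraction.
- **Conservation tests** against an ortholog proteome (internal
  Smith–Waterman, BLOSUM62 11/1, Karlin–Altschul bits): the
  N-terminal-extension test (uORF-extended vs scrambled-extension
  queries; statistic = bit-score improvement specific to the real
  extension) and the first-vs-second-ATG CDS-membership test (nested
  queries s0, s1, s2).
- **Bayes classifier**: P(translated | K, L) as the density ratio of
  conserved class-1 (positive) vs class-2 (negative) training surfaces on
  a 30×30 grid of 2^K × log₁₀(length), prior 0.5, with ROC/AUC.
- **Synthetic genomes with ground truth** (`generate_genome`): GC 0.65,
  multi-exon transcripts on both strands, implanted class-1 uORFs with
  calibrated context strength and ortholog-conserved extensions — the
  end-to-end validation substrate for everything above.

## Worked example

Generate a 200-transcript genome in which every transcript carries a
class-1 uORF and a known 50% are "translated" (strong initiator context,
conserved extension), then run the whole pipeline:

```r
library(uorfscan)
spec <- synthetic_spec(n_transcripts = 200, cds_meanlog = log(60),
                       cds_sdlog = 0.5, fraction_class1_implanted = 1,
                       fraction_translated = 0.5)
res <- run_all("demo_out", seed = 42, spec = spec, proteome = TRUE,
               n_random = 10000)
print(res$inventory); print(res$mixture); print(res$extension)
print(res$roc)
mean(res$prob_table$p_translated)
```

```
uORF inventory over 200 transcripts
  transcripts with class 1: 200  class 2: 78  class 3: 82
  none: 0
  candidate ATGs  class 1: 273  class 2: 104
mixture fit: c1 = 0.5027, c2 = 0.4733, PVE = 0.8352 (40 bins)
extension conservation test over 200 class-1 uORFs
  median improvement 11.75 bits; high-BLASTP (top 25%): 50; > 4 bits: 100
ROC curve: 112 points, AUC = 0.9986
[1] 0.503
```

Reading the numbers: the class-1 Kozak-score distribution decomposes as a
50:47 mixture of the reference-initiator and random score distributions —
recovering the implanted 50% translated fraction; the conservation test
flags exactly the 100 transcripts whose extensions were carried into the
ortholog proteome (improvement > 4 bits); and the Bayes classifier,
trained on that conserved subset vs class-2 uORFs, assigns a mean
posterior of 0.503 across all class-1 uORFs — again the implanted 0.5.
Per-uORF posteriors land in `demo_out/uorf_probabilities.tsv`:

```
transcript_id atg_pos length_codons kozak_score improvement p_translated
tx00001           167            58        8.49       68.57        0.999
tx00002            14            48        7.99       51.23        0.988
...
```

Real inputs run through the same entry point:
`run_all(out, seed, fasta = "genome.fa", gff3 = "annotation.gff3",
proteome = "orthologs.fa")`.

The `analysis/` directory holds numbered driver scripts
(`01_simulate.R` … `07_dorfs.R`) that run the same stages as a narrated
study — inventories and ATG frequencies, randomized-control comparisons,
Kozak matrix and mixture, conservation tests, Bayes/ROC, and the dORF
scan — writing their tables under `results/`.

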