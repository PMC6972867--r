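# flapr

Design of **fluctuation-regulated affinity proteins (FLAPs)**: small
antibody mimetics built by grafting an antigen-binding CDR hexapeptide
from an antibody into a non-immunoglobulin scaffold site that structurally
immobilises it.

## The problem

Antibodies bind antigen through their CDR loops, and the longest
contiguous run of antigen-contacting residues in most antibody chains is
about six amino acids. A hexapeptide cut out of a CDR usually loses its
affinity because, free of the antibody framework, it is conformationally
disordered. The FLAP strategy restores affinity by grafting the peptide
into a **graft-acceptor (GA) site** of a small scaffold — a loop position
whose flanking structure holds any inserted hexapeptide rigid. flapr
implements the computational pipeline for this strategy, for protein
engineers and structural bioinformaticians who want to screen scaffolds
and CDRs before committing to wet-lab work:

1. **GA-site identification.** Candidate sites are loop hexapeptide
   windows sequentially flanked by α-helices, β-strands or
   disulfide-bonded cysteines. Filters: every residue solvent accessible
   (SASA > 15 Å², strict), mean heavy-atom RMSF < 1.0 Å
   (the constrained-and-solvent-accessible, **CSA**, rule; < 1.5 Å defines
   the looser "constrained" class). Each CSA site is then grafted in
   silico with all 20 homo-hexapeptides (A6 … Y6, spanning the extremes of
   the 20⁶ = 6.4×10⁷ hexapeptide space) and re-profiled; it is a **GA
   site** iff max over the 20 grafts of the mean window RMSF < 1.5 Å.
2. **CDR hexapeptide extraction.** Every 6-mer window overlapping a CDR of
   an antibody–antigen complex is mutated to AAAAAA and the binding-energy
   loss ΔG(ala6) − ΔG(wt) is computed with a simplified interface score
   (Lennard-Jones + screened Coulomb with ε(r) = 4r). The top-ranked
   windows carry the paratope.
3. **Design generation.** Selected peptides × GA sites (named
   `Sca8-1-TH3`-style) are built by backbone-preserving residue
   replacement with a discrete rotamer search, then ranked by grafted-
   window RMSF and heavy-atom RMSD to the source CDR conformation.

Fluctuations come from either a conformational ensemble (multi-model PDB;
Kabsch superposition, RMSF about the mean) or a Gaussian network model
(Kirchhoff matrix on Cα contacts at 7.5 Å, pseudoinverse diagonal, scaled
by an explicit calibration constant). Secondary structure is assigned by
Kabsch–Sander hydrogen-bond analysis; SASA by Shrake–Rupley. A synthetic
fixture generator (`fixture_structure()`, `fixture_ensemble()`) produces
scaffolds, ensembles and a toy antibody–antigen complex with designed
ground truth, so the entire pipeline is testable offline.

## A worked example

```r
library(flapr)

scaffolds <- list(
  clamp = fixture_structure("clamped_hairpin", id = "clamp"),  # designed GA
  free  = fixture_structure("helix_loop_helix", id = "free"))  # designed not-GA
cal <- enm_calibration(fixture_structure("hairpin"), target = 0.8)
backend <- function(s) rmsf_from_enm(s, calibration = cal)

scan <- scan_scaffolds(scaffolds, backend = backend)
scan
#> # Scaffold scan: 2 scaffold(s)
#> # A tibble: 2 × 5
#>   scaffold enumerated    sa constrained   csa
#>   <chr>         <int> <int>       <int> <int>
#> 1 clamp             1     1           1     1
#> 2 free              1     1           0     0
```

Each scaffold contributes one flanked loop window; both are solvent
accessible, but only the disulfide-clamped loop is constrained (mean RMSF
below 1.0 Å on the calibrated scale), so only it reaches the CSA stage —
the funnel can only narrow. Homo-hexapeptide profiling then confirms it as
a GA site:

```r
ga <- profile_ga(scan, scaffolds, backend)
glance(ga)
#> # A tibble: 1 × 7
#>   site_name max_rmsf threshold verdict complete motif ca1_ca6_dist
#>   <chr>        <dbl>     <dbl> <chr>   <lgl>    <chr>        <dbl>
#> 1 clamp-1      0.767       1.5 GA      TRUE     SLS           4.90
```

The worst of the 20 homo-hexapeptide grafts still fluctuates only
0.767 Å — every graft is immobilised, so `clamp-1` is a graft acceptor
(a strand-loop-strand site whose first and sixth Cα sit 4.9 Å apart). The
free crossover loop profiles at 1.84 Å and is called not-GA. On the toy
complex, the alanine-hexapeptide scan ranks the window carrying all six
designed salt bridges first (binding-energy loss 54.5 model units;
windows outside the interface lose exactly 0):

```r
cx <- complex_spec(fixture_structure("toy_complex"), "R", "L",
                   cdr = tibble::tibble(chain = "L", name = c("C1", "C2"),
                                        start = c(8L, 21L), end = c(18L, 27L)),
                   chain_prefix = c(L = "TH"))
cdr <- extract_cdr(cx, top_k = 1)
cdr$selected             # the hot window: the six designed arginines
#> # A tibble: 1 × 2
#>   name  seq
#> 1 TH6   RRRRRR
designs <- design_grafts(ga, cdr$selected, scaffolds, backend)
designs$mean_rmsf        # grafted window on the GA host stays < 1.5 A
#> [1] 0.7667
```

`plot_funnel()`, `plot_ga_matrix()` and `autoplot()` methods give ggplot
views of each stage; `tidy()`/`glance()` return tibbles. A command-line
front end (`inst/scripts/flap.R`) exposes the same pipeline as
`scan-scaffolds`, `profile-ga`, `extract-cdr`, `design` and `fixtures`
subcommands driven by a YAML config
(`inst/extdata/config_template.yml`) in which every threshold is explicit.

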