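# lassofold

Coarse-grained folding simulation and topology analysis of **complex
lasso proteins** — proteins whose backbone threads a covalent loop closed
by a disulfide bridge. The package is aimed at people studying how
self-entangled proteins reach their native topology: it simulates folding
trajectories at the Cα level, detects when and how the lasso forms, and
tunes the model's force field for reproducible folding.

Three ingredients:

* **The elastic folder model (EFM).** A minimalistic Cα chain — WCA
  sterics, FENE bonds — whose folding drive is purely structure-based
  bending and torsion potentials,

      U_bend = k_i (θ_i − θ_i⁰)²,
      U_tor  = k1_i [1 − cos(φ_i − φ_i⁰)] + (k1_i/3) [1 − cos 3(φ_i − φ_i⁰)],

  parameterized so the reference (native) conformation is the energy
  minimum. Disulfide bridges are truncated, force-shifted LJ wells with
  their minima at the native cysteine pair distances, switched on under
  oxidizing conditions. A Clementi-type Gō model (12-10 native contacts)
  is included for comparison. Dynamics is underdamped Langevin (BAOAB,
  dt = 5·10⁻⁴ τ_MD) from stretched random configurations.

* **Topology descriptors.** The continuous *lasso variable* L ∈ [0, 1]
  scores whether the reduced, fan-triangulated covalent-loop surface is
  pierced with the native signature (products of Fermi switches on
  geometric margins), and the *Gauss linking number*

      G = (1/4π) ∮∮ (r₁ − r₂) · (dr₁ × dr₂) / |r₁ − r₂|³

  is evaluated exactly over polygonal curves (segment-pair solid angles),
  with the loop integrated between the bridge cysteines and a split-tail
  orientation so double piercings add instead of cancelling. Folding is
  declared only when both √F < 0.9 (RMSD from native) and L > 0.9, and
  successful trajectories are classified into **threading**,
  **bridge-reopening** and **open-loop** pathways from the order of loop
  closure (t_b) and topology formation (t_k).

* **Evolutionary force-field optimization.** The per-angle stiffnesses are
  tuned by a stochastic Metropolis search (SFFO: mutate one constrained
  coefficient pair, test with folding trajectories, accept with
  min{1, exp(⟨F⟩_old − ⟨F⟩_new)}), and its population extension (MFFO:
  rank by an exponentially averaged folding-probability proxy, keep the
  winners, rebuild the rest by crossover with random low-fit parents).

Because production systems are large, the package also ships a
deterministic **mini-lasso generator**: desk-scale L1/L2 lasso structures
on which every component — energetics, dynamics, descriptors, statistics,
optimizer — runs in seconds to minutes.

## Worked example

```r
library(lassofold)

# synthetic desk-scale lasso protein (L2: the tail pierces the loop twice)
sys <- make_mini_lasso(n_loop = 12, n_tail = 10, lasso_class = "L2", seed = 1)
lasso_variable(sys$conf, sys$spec)   # 0.9997645  (native topology, L ~ 1)
lasso_gauss(sys$conf, sys$spec)      # 1.192086   (G >~ 1: double piercing)

# homogeneous elastic folder model, oxidizing conditions
params <- model_parameters()                  # T = 0.1, dt = 5e-4
ff     <- efm_forcefield(n_beads(sys$conf))   # k_bend 36.5, k1_tor 38.5
trajs  <- run_folding_ensemble(sys, ff, n_traj = 8, tau_run = 300,
                               seed = 42, oxidizing = TRUE)

sigma_b1 <- bridge_parameters(sys$ref)$sigma_b[1]
res <- analyze_ensemble(trajs, bridge_threshold = 1.5 * sigma_b1,
                        reopen_threshold = 2.0 * sigma_b1)
res
#>   t_b t_k t_f success     label
#> 1  14  13  13    TRUE open-loop
#> 2  33  31  31    TRUE open-loop
#> 3  37  34  34    TRUE open-loop
#> 4   8  10  10    TRUE threading
#> 5  16  14  14    TRUE open-loop
#> 6  15  12  12    TRUE open-loop
#> 7  13  11  11    TRUE open-loop
#> 8  13  11  11    TRUE open-loop
pathway_statistics(res)[c("P_f", "P_threading", "P_reopening", "P_open_loop")]
#> $P_f          [1] 1
#> $P_threading  [1] 0.125
#> $P_reopening  [1] 0
#> $P_open_loop  [1] 0.875
```

Each row is one trajectory: `t_b` is the first sustained closure of the
cysteine bridge, `t_k` the first sustained native topology (L > 0.9),
`t_f` the arrival in the native basin (all in τ_MD; conditions must hold
for 10 τ_MD). Here most runs form the lasso *before* the bridge closes —
the open-loop pathway; one threads the already-closed loop. On this small
system at these settings all eight runs fold; larger ensembles in
reducing vs oxidizing conditions show the bridge's topological barrier as
a lower P_f (see the acceptance script below).

The optimizer works the same way at desk scale:

```r
refsys <- folding_reference(sys$conf, sys$ref, model_parameters())
cfg <- optimizer_config(n_test = 4, tau_run = 1.5, m_cycle = 4, N_K = 6,
                        N_win = 2, N_low = 2, alpha = 0.3, sample_every = 250)
fit <- mffo_run(refsys, cfg, cycles = 10, master_seed = 1)
fit$history      # per-cycle best/mean folding proxy
```

Production-scale settings (a 121-residue lasso protein, 2048 trajectories
of 1.5·10⁴ τ_MD, 30 MFFO cycles of m = 50 with N_K = 16) are kept as
editable YAML configs under `inst/extdata/configs/`; they require the
protein's PDB file and hours–days of CPU. A thin command-line wrapper is
installed at `exec/lassofold` (`prepare`, `simulate`, `fixtures`).

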