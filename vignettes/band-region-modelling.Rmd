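---
title: "Band-region modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-region modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandregion)
```

## The model

A degrader-recruited ubiquitination complex holds the protein of interest
(POI) against a Cullin-RING ligase whose RING subunit carries the
ubiquitin-charged E2 enzyme. Ubiquitin transfer needs the POI lysine Nζ to
approach the E2 catalytic cysteine Sγ closely enough for the conserved E2
acidic site to attract and deprotonate it; mere colocalisation of E2 and
POI is not sufficient. Two sources of flexibility decide which lysines can
be approached:

* **collective scaffold motions** — the elongated Cullin arm breathes
  through a few low-frequency modes (an open–close motion and a twist are
  the dominant pair), displacing the E2 relative to the POI; and
* **the RING hinge loop** — a ~5-residue unfolded linker through which the
  RING domain, with the E2–ubiquitin module docked on it, dangles from the
  scaffold. Rotating its backbone dihedrals sweeps the catalytic cysteine
  through a large but bounded spatial envelope.

The intersection of that envelope with the POI surface is the *band
region*. A surface lysine is a candidate ubiquitination site when (i) some
sterically admissible conformation brings Sγ within the contact threshold
of its Nζ, and (ii) its side-chain charge is not pinned by a salt bridge to
a neighbouring Asp/Glu carboxylate, which both shields the charge the E2
acidic site must attract and blocks the conformational adjustment the
reaction needs. Chemical exclusion therefore overrides distance; hydrogen
bonds alone are reported but do not exclude.

## Pipeline stages and parameters

All units are angstrom and degrees; author residue numbering from input
files is never renumbered.

| parameter | default | meaning |
|---|---|---|
| `enm.cutoff` | 15 | Cα contact distance of the elastic network |
| `enm.gamma` | 1 | uniform spring constant (arbitrary units) |
| `enm.n_modes` | 5 | "major" (lowest nonzero-frequency) modes animated |
| `enm.n_frames` | 28 | frames per one sinusoidal animation cycle |
| `enm.rmsd_max` | 10 | Cα-RMSD envelope of each animation |
| `enm.secondary_frame_picks` | 5,10,15,20,25 | mode-2 frames reseeding mode 1 |
| `sampler.n_draws` | 10000 | random φ/ψ draws per conformer |
| `contact_threshold` | 8 | Sγ–Nζ distance counting as contact (inclusive) |
| `clash_cutoff` | 2.5 | heavy-atom clash distance (strict) |
| `anchor_max` | 50 | pose-level anchor feasibility bound (strict) |
| `salt_bridge_max` | 4.0 | Nζ–carboxylate-O distance defining a salt bridge |
| `hbond_max` | 3.5 | Nζ–acceptor distance defining a hydrogen bond |

With the defaults, the mode stage emits 5 × 28 = 140 conformers and the
loop stage evaluates 140 × 10,000 = 1,400,000 conformations. The animation
amplitude follows `a_t = A sin(2πt/n_frames)` with `A = rmsd_max · √N`
(unit-norm mode vector over N Cα nodes), so the envelope maximum is
attained exactly and the final frame is the parent structure — which also
means the loop stage always samples the unperturbed complex.

### Numerical choices

* **Normal modes.** The anisotropic-network Hessian uses the standard
  super-element `-(γ/d²) r rᵀ` with diagonal blocks closing each row to
  zero, and is diagonalised densely (`eigen`, symmetric). Eigenpairs below
  `1e-8 ×` the largest eigenvalue are discarded as rigid-body modes — a
  scale-free criterion that also handles disconnected networks (each extra
  component contributes six more zero modes). Eigenvector sign is fixed by
  making the largest-magnitude component positive; "mode 1" is the lowest
  nonzero frequency. All-atom frames are reconstructed by translating every
  atom rigidly with its residue's Cα node: the simplest scheme that
  conserves residue geometry exactly, at the cost of slightly distorted
  inter-residue bonds in perturbed frames (they are treated as what they
  are — coarse perturbations, not refined structures).
* **Hinge kinematics.** Setting a φ/ψ rotates, about the central bond,
  everything C-terminal to it in the loop's chain plus the attached rigid
  group; the ψ of the loop's last residue uses the next residue's N for its
  axis while that residue already belongs to the moving group. Set/measure
  are exact inverses (tested to 1e-6°) and compositions conserve all bond
  lengths and angles identically — they are pure rotations. Random
  sampling redraws *every* loop torsion independently and uniformly on
  [-180°, 180°) each draw (the maximal-entropy reading of "random angles";
  a one-at-a-time perturbation mode was considered and rejected for the
  default because it mixes far more slowly). No Ramachandran weighting and
  no loop closure: the loop is anchored at its N-terminal side only.
* **Streaming evaluation.** The loop stage never materialises
  conformations. Because the loop is a serial kinematic chain, each draw is
  summarised by one rigid transform per chain segment; composing those
  transforms vectorised across draws gives probe positions, site distances
  and clash flags directly. The streaming path is checked atom-for-atom
  against the one-conformer-at-a-time reference implementation in the test
  suite.
* **Clash filter.** Heavy-atom pairs between the moving set and the rest of
  the complex closer than the strict cutoff discard a conformation; pairs
  within the same or adjacent residues of one chain are exempt, which
  covers the covalent seam (bonded and 1-3 neighbours) at the loop
  boundary. The cutoff sits in configuration because no universal value
  exists; the synthetic ground truth is built with ≥ 2 Å margins so
  verdicts are robust to ± 0.5 Å changes.
* **Boundary rules.** "Within the threshold" is read inclusively (exactly
  8 Å counts as contact); the pose anchor criterion "less than 50 Å" is
  strict (exactly 50 Å is removed). One clash-free contact conformation
  suffices for an in-band verdict by default; a stricter
  `min_contact_frames` knob exists because "multiple conformations" was
  never quantified.
* **Superposition.** Kabsch via SVD with a determinant correction, one
  shot; collinear pairings are rejected. No outlier-trimming by default
  (reproducibility over mimicry of unstated refinement cycles); an
  optional single 2σ-trim pass exists. Scaffold pairing is by atom
  identity, or by global sequence alignment (match +1, mismatch −1, linear
  gap −2) when chains differ.
* **Homolog displacement RMSD.** The separation of two homologs occupying
  different poses in superimposed complexes is computed by the duplicate
  trick: duplicate chain a, superpose the duplicate onto chain b over
  sequence-matched Cα pairs, and report the Cα RMSD between a and its own
  moved duplicate. This is identically 0 for identical inputs and measures
  pose displacement, not fold difference; the conventional fit RMSD over
  matched pairs is attached as an attribute. The published comparison this
  reproduces depends mildly on alignment parameters, hence the declared
  simple scores.
* **Greedy refinement.** The manual "fine-tune the loop until ~3 Å" step is
  replaced by a documented algorithm: propose a Gaussian 15° change of one
  random loop torsion, accept iff the catalytic distance decreases and no
  clash appears, stop at the target or after `max_iter` proposals. It is
  seeded, monotone by construction, and returns the input with a warning
  flag (not an error) when it cannot improve.
* **Surface exposure.** Shrake–Rupley with a deterministic spiral
  quadrature (960 points, probe 1.4 Å), normalised by the same residue in
  an extended Gly-X-Gly reference. The relative-SASA filter (≥ 0.25) is
  applied only during automatic site discovery; explicitly listed sites
  are always evaluated.
* **Point mutants.** Arg/Gly→Lys mutants are built with a single extended
  rotamer (all side-chain χ = 180°, ideal bond lengths/angles) on an
  untouched backbone. The original mutagenesis tool's rotamer choice is
  unknowable; the extended stand-in is declared rather than guessed, and
  classification depends on Nζ reachability over thousands of backbone
  conformations, not on one rotamer.

## Escalation tiers

Sampling breadth escalates through three strictly nested tiers:
`modes_only` evaluates the 140 mode conformers directly; `modes_loop` adds
the random loop draws on each of them; `combined_loop` additionally reseeds
the first mode from frames 5–25 of the second mode and samples the loop on
those restarts too. Each tier re-evaluates everything the previous tier
evaluated (the per-frame seeds are preserved), so escalation can only add
contact evidence: an in-band site can never become out-of-band at a higher
tier. Escalation is applied per run; a per-site schedule would give the
same verdicts by monotonicity.

## The synthetic test-bed and what it does (not) show

`make_hinge_complex()` builds an anchored chain with a five-residue hinge
(the canonical hinge length), a short rigid group carrying an SG probe
atom, and a static chain of lysine sites with known labels:

* *reachable* sites are placed 4 Å beyond a densely revisited probe
  position (chosen to maximise the fraction of clash-free draws inside the
  contact ball), giving a minimum achievable distance ≈ 4 Å — 2 Å inside
  the 8 Å threshold — and a per-draw contact probability of a few percent;
* *unreachable* sites are placed beyond the hinge's conservative reach
  bound plus the threshold plus margins covering the worst-case relative
  displacement under mode animation at the canonical 10 Å envelope, so the
  label holds at every sampling tier by construction;
* *excluded* sites are reachable lysines with a glutamate carboxylate
  oxygen planted 3.0 Å from Nζ.

Labels are **verified at generation time** by an independent 400-draw
sampling scan (reachable: minimum clash-free distance ≤ 6 and contact
fraction ≥ 2%; unreachable: no approach under 10 Å; excluded: the salt
bridge is detected), and generation fails loudly rather than emit an
unverified complex. Lever lengths default to 3 + 5 + 3 residues: long
enough for genuine kinematic complexity, short enough that the probe cloud
stays dense and recovery statistics are stable.

What passing these tests shows: the kinematics, filtering, counting and
verdict logic are exact, deterministic and scale to the canonical 1.4
million evaluations. What they do not show: anything about real protein
energetics. The synthetic complexes have ideal geometry, no side-chain
repacking, no electrostatics, and a POI that is not physically connected to
the scaffold — on such a complex the network model's low-frequency modes
are dominated by the floating parts, which is why the planted unreachable
margin accounts for mode displacement explicitly. Real-complex analyses
should treat the mode stage as a coarse flexibility proxy, as the protocol
intends.

The sampling sizes used throughout the suite (400-draw verification scans,
2000-draw recovery classification, 100 seeded complexes, one full
140 × 10,000 run) were chosen as the smallest sets whose pass/fail
behaviour is statistically stable: at a ≥ 2% verified contact fraction,
2000 draws miss a reachable site with probability below 10⁻¹⁷.

## Pose triage

Externally generated ternary poses (this package does not dock) are
filtered by the strict anchor rule, clustered with DBSCAN on the Cα RMSD of
the mobile subunit after superposing every pose on the first pose's E3
selection (the E3 frame is the natural choice because poses vary the POI
orientation against a fixed ligase), and the lowest-score pose among filter
survivors is selected, ties breaking to the lowest index. `eps = 4 Å` and
`min_pts = 3` are configuration defaults, documented as conventional rather
than derived; ranking is global with cluster annotation, since a
per-cluster-representative scheme was never specified.

## Known limitations

* Mode animation is harmonic extrapolation; 10 Å excursions are far outside
  the linear regime and are used as a sampling device, not as predicted
  structures.
* Uniform torsion sampling ignores Ramachandran statistics; accessible
  conformations are over-counted relative to a physical ensemble, which is
  conservative for ruling sites *out* but not a free-energy statement for
  ruling them *in*.
* The clash filter considers the moving set against the remainder only;
  loop self-collisions are not filtered (they are rare and harmless for
  distance classification).
* Chemical exclusion is a geometric screen on one conformation; it does not
  model pKa shifts or the acidic-site interaction itself, and the E2
  aspartate position is reported as annotation only, never used as a
  criterion.
* mmCIF, hydrogens, and full rotamer libraries are out of scope.
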