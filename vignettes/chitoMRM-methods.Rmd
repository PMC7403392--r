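---
title: "Detecting lipo-chitooligosaccharides by in-silico MRM: models and methods"
author: "chitoMRM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lipo-chitooligosaccharides by in-silico MRM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chitoMRM)
```

## The problem

Lipo-chitooligosaccharides (LCOs, the rhizobial "Nod factors") and short
chitooligosaccharides (COs) are symbiotic signals: chitin backbones of a few
N-acetylglucosamine (GlcNAc) residues, in the LCO case N-acylated at the
non-reducing end and optionally decorated with sulfate, methyl, carbamoyl,
acetyl, fucosyl or methylfucosyl groups. Screening culture exudates for
these molecules by tandem mass spectrometry requires (i) a database of every
plausible structure with its precursor and fragment masses, (ii) a reduced
multiple-reaction-monitoring (MRM) panel that an instrument can actually
monitor, and (iii) rules for turning matched chromatographic peaks into
detection calls with an honest confidence level. `chitoMRM` implements that
pipeline end to end and ships a synthetic-data generator so every stage is
testable without instrument data.

## Mass model

All masses are monoisotopic, computed from integer element counts over
C, H, N, O and S with the IUPAC atomic masses hard-coded to >= 6 decimals
(`mass_constants()`), so results do not depend on any external table. The
in-chain GlcNAc residue is C~8~H~13~NO~5~ (203.0794 Da); a CO of *n*
residues is *n* residues + H~2~O; an LCO swaps the N-acetyl of the
non-reducing terminal residue (-C~2~H~2~O) for a fatty acyl group
C~c~H~2c-2-2d~O~1+h~ (*c* carbons, *d* double bonds, *h* hydroxyls) and adds
the net deltas of its substituents. Ionisation is fixed at the singly
protonated adduct [M+H]^+^ (proton mass 1.007276 Da, distinct from the
hydrogen atom): these compounds are observed singly charged in positive
mode on triple quadrupoles. Unit-resolution ("nominal") m/z is obtained by
rounding half away from zero, which reproduces the printed CO assay values:

```{r nominal}
vapply(3:6, function(n) nominal_mz(precursor_mz(co_structure(n))), integer(1))
nominal_mz(b_ion_mz(co_structure(3), 1))
```

Average (isotope-weighted) masses, isotope patterns and other adducts
(Na^+^, K^+^) are out of scope; monoisotopic [M+H]^+^ is the standard
operating point for unit-resolution MRM work on these compounds.

## Fragmentation model

Only glycosidic B ions are generated: collision-induced dissociation of
protonated chitin oligomers is dominated by the oxocarbenium series, and the
database this package mirrors pairs precursors exclusively with B ions. The
B~i~ ion keeps the *i* non-reducing-side residues, including the acyl chain
and any R2-R4 substituents, plus a proton; substituents on the reducing
terminal residue (R5, R6) never appear in any B ion. Two consequences are
worth noting because tests rely on them: the B-ion series is strictly
increasing in the cleavage index, and reducing-end-only modifications
(sulfation, fucosylation) leave the entire B-ion list unchanged, so e.g. a
sulfated and non-sulfated LCO pair differ only in precursor m/z.

## Structure grammar

The enumerable space is the Cartesian product of backbone length, acyl
chain, and one substituent per position R2-R6. Positions R2-R4 sit on the
non-reducing terminal residue (R1 being the acyl chain), R5-R6 on the
reducing terminal residue; each substituent code carries an allowed-site
class, so chemically implausible placements (sulfate on the non-reducing
end, carbamoyl on the reducing end) are rejected at construction.

Defaults, chosen once as the package's study conditions:

* backbone lengths 3-5 (the range described for fungal and rhizobial LCOs);
* acyl chains C12-C22 with 0-3 double bonds, **even chain lengths only**:
  natural fatty acids are built two carbons at a time, and an odd-chain acyl
  is exactly isobaric with the corresponding even-chain + N-methyl
  structure — a degeneracy no unit-resolution instrument can resolve, so
  admitting both would only plant unresolvable ties in the database. Any
  other library (including odd chains) can be supplied explicitly.
* allowed substituents: R2 ∈ {H, Me}, R3 ∈ {H, Ac, Cb}, R4 ∈ {H, Cb},
  R5 ∈ {H, Ac}, R6 ∈ {H, S, Fuc, MeFuc, FucS, Ac}. N-methyl is included at
  R2 although it is absent from some published substituent lists, because
  methylated structures are among those actually detected in fungal
  exudates.

Structures are named in standard Nod-factor nomenclature
(`LCO-IV(C16:0,S)`, `CO4`) with the non-H substituent codes sorted, and the
canonical name is the deduplication key. This is a deliberate design
choice: two assignments with the same code multiset (e.g. O-acetyl at R3
vs. R5) collapse to one database entry. Positional isomers of the same
composition are not separable by the precursor/B-ion masses this assay
records unless they straddle the cleavage site, and the collapse keeps the
name a stable, order-independent identifier. The full positional assignment
remains available on the structure objects themselves.

The default grammar enumerates 6,192 distinct structures (18,576
transitions). The published in-house database this mirrors is far larger
(tens of thousands of precursors) because its exact grammar — acyl fine
structure, multiple hydroxylations, conjugated variants — lives in
supplementary material distributed with the original study; `db_stats()`
reports structure, unique-precursor and unique-transition counts for any
grammar so a user holding that file can tune a configuration toward it, but
exact reproduction of those totals is deliberately not promised. Because
the ambiguity of "precursor ions" (entries vs. distinct m/z values) cannot
be resolved from the text, `db_stats()` reports both interpretations.

## Transition database and panels

`build_transition_db()` emits one record per (structure, B ion) with
deterministic ordering; uniqueness of m/z values is assessed at 4 decimal
places — below instrument resolution, above floating-point noise.
`select_panel()` restricts the database to named structures (all their
transitions), mirroring how a practical assay monitors only a few hundred
transitions to preserve sensitivity; a size cap truncates after name sort.
Expected retention times are optional metadata, populated from synthetic
standards when available; no retention-time prediction is attempted.

## Peak picking and detection confidence

A trace's baseline level is estimated by its median and the baseline noise
by its median absolute deviation — both robust to an elution peak occupying
a small fraction of the trace. Apexes are plateau-tolerant local maxima
rising above the baseline by at least `max(min_height, snr_threshold *
noise)`, and accepted apexes must be separated by one full width at half
maximum (taller peaks win). The default `snr_threshold` is 5, the
conventional LC-MS detection limit; at 3, a 1,000-point noise trace is
expected to produce occasional spurious apexes, which the co-elution logic
then has to absorb.

Traces are assigned to panel transitions when both precursor and product
m/z are within `mz_tolerance` (default 0.5 Da, unit resolution); an
ambiguous trace goes to the nearest transition with a logged warning so
results stay deterministic. Per structure, apexes across transitions are
grouped by co-elution (default window 0.1 min) and the confidence tier
follows the evidence: two or more co-eluting transitions give a
high-confidence call; exactly one transition is accepted only at the
structure's expected retention time, as a low-confidence call; a single
uncorroborated transition is reported as no detection, flagged in the
output. These tiers mirror how targeted LCO surveys report their hits
(filled vs. outlined symbols per species).

Untargeted annotation (`match_untargeted()`) emulates full-scan precursor
selection followed by product-ion accumulation: candidates are restricted
to 3-6 GlcNAc backbones, must match the precursor within 0.3 Da, and need
at least 2 B ions present among the spectrum's products; ranking is by
matched-product count, then precursor error, then name. Quantification is
explicitly out of scope — the method detects, it does not measure
abundance.

## Synthetic data

The generator is the package's stand-in for exudate injections, and its
defaults are the fixed study conditions of all shipped analyses: Gaussian
elution peaks (sigma 0.05 min) at the planted structure's retention time on
every non-dropped transition; apex amplitudes uniform in 500-2,000 counts;
a 1-11 min acquisition window at 0.01 min steps (matching a short
reversed-phase gradient, with retention times drawn uniformly in-window
when unspecified); additive Gaussian baseline noise (sd 5 counts) on a
constant detector baseline of three noise standard deviations, clipped at
zero — the offset keeps the clipped baseline effectively Gaussian, as on a
real detector, so the median/MAD noise model holds. Decoy peaks are placed
both on non-planted panel transitions at random times (stressing co-elution
logic) and on off-panel m/z pairs (stressing tolerance logic). Everything
is reproducible to the byte under a fixed seed.

What the generator does not emulate — and therefore what passing tests do
not show about real data: ion suppression and matrix effects, tailing or
asymmetric peak shapes, retention-time drift between runs, correlated
noise, in-source fragmentation, and isotope envelopes. Recovery results on
synthetic data are a check of the pipeline's logic, not a validation of
instrumental sensitivity.

Untargeted spectra are generated per structure as the full true B-ion list
plus a configurable number of uniform-random noise products. With 200
spectra drawn from the default database at 2 noise products each, rank-1
annotation accuracy at 0.3 Da / min 2 products is 1.0 in the shipped
benchmark (`analysis/04_untargeted.R`); ties are impossible there by
construction of the even-chain grammar, and the deterministic tie-break
(matched count, then precursor error, then name) makes the ranking stable
regardless.

## Numerical and degenerate-input choices

* Rounding: nominal m/z rounds half away from zero (reproducing all five
  printed CO-assay values); dedup rounding is at 4 decimals.
* Empty inputs: an empty trace yields no peaks (not an error); an empty
  spectrum list yields no annotations; an empty panel selection is a valid
  empty panel. An empty acyl library or a planted structure missing from
  the panel are configuration errors.
* A structure whose substituent deltas would drive any element count
  negative is rejected as chemically invalid.
* Problem sizes in the shipped tests and analyses — grammars up to ~6,000
  structures, 200-spectrum benchmarks, 10-structure recovery panels — were
  chosen as comfortably representative for a desk-scale study of the
  method's behaviour.

## Known limitations

Stereochemistry, linkage isomers and acyl fine structure beyond
carbon/double-bond/hydroxyl counts are not modelled. Charge states other
than +1 and adducts other than the proton are not generated. Collision
energies and other instrument voltages are acquisition settings, not
database properties, and are ignored. Retention times are metadata, never
predictions. The evidence matrix's bioassay columns are pass-through inputs
from wet-lab scoring; the package never computes them.
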