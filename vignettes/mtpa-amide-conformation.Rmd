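---
title: "The solid-state conformation of MTPA amides: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The solid-state conformation of MTPA amides: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtpaconf)
```

## Why MTPA-amide conformation matters

Mosher's acid (MTPA, 3,3,3-trifluoro-2-methoxy-2-phenylpropanoic acid) is the
workhorse chiral derivatizing agent for assigning the absolute configuration
of amines and alcohols by NMR. The method works only because the MTPA amide
adopts a predictable conformation: the amide carbonyl is roughly
synperiplanar to the CF3 group, the amine's methine hydrogen lies near the
carbonyl plane, and the phenyl ring shields one substituent of the amine in a
reproducible way. `mtpaconf` turns the crystallographic evidence for that
conformational model into a reusable, tested pipeline: from crystal
structures (or the packaged reference torsion table) through atom-role
assignment, torsion descriptors, enantiomer normalization and conformer
classification, to the survey statistics.

## The seven torsion descriptors

Atom numbering follows the survey convention: C1 is the amide carbonyl
carbon (O1 its oxygen, N the amide nitrogen), C2 the quaternary stereocenter
carrying the CF3 carbon C3, the methoxy oxygen O2 (methyl C4) and the phenyl
ipso carbon C5. C1' is the alpha atom of the N-substituent synperiplanar to
O1 (R^sp), X1'' the alpha atom of the antiperiplanar substituent (R^ap),
H1' the methine hydrogen on C1'.

| descriptor | atoms | meaning | selection rule |
|---|---|---|---|
| theta1 | O1-C1-C2-C3 | carbonyl vs CF3 | — |
| tauF | C1-C2-C3-F3 | CF3 rotamer | F3 = fluorine maximizing the absolute torsion, hence \|tauF\| >= 120 |
| tauSp | C1'-N-C1-O1 | amide planarity, sp side | sp side = \|torsion\| <= 90 |
| tauAp | X1''-N-C1-O1 | amide planarity, ap side | null when R^ap = H |
| tauH | H1'-C1'-N-C1 | methine orientation | null without a unique methine H |
| theta2 | O2-C2-C5-C10 | phenyl twist | C10 = ortho carbon with the smaller absolute torsion, hence \|theta2\| <= 90 |
| tauOMe | C1-C2-O2-C4 | methoxy rotamer | — |

Torsions follow the IUPAC/Klyne–Prelog sign convention and live on
(-180, +180] degrees; a computed value of exactly -180 is reported as +180 so
every angle has one representation. The two-plane `atan2` formulation is
numerically stable near 0 and 180 degrees and is cross-checked in the test
suite against an independently derived projection formula on random
geometries to 1e-9 degrees.

## Enantiomer normalization

Crystal structures deposit both R-acid and S-acid MTPA amides. All
statistics are computed in the R-acid frame: for an S-acid moiety every
non-null torsion is negated (mirror-image processing), with +180 the fixed
point of the sign reversal. `normalize_to_R()` is idempotent, and the whole
pipeline satisfies a mirror theorem — a structure and its point inversion
yield identical normalized descriptors and conformer classes, with raw
torsions negated and the C2 descriptor flipped — which the suite asserts on
hundreds of generated structures.

The C2 descriptor itself needs no general CIP machinery: by construction of
the moiety match the four substituents of C2 are always O2, CF3-carbon,
amide carbon and phenyl ipso, whose first-sphere CIP order is fixed
(O > C(F,F,F) > C(O,O,N) > C(C,C,C)). The descriptor is the sign of the
scalar triple product of the bond vectors to the three highest-priority
substituents, validated against a hand-built reference tetrahedron. A full
CIP engine would add scope without adding correctness for this substructure.

## Conformer classes and amide Z/E forms

* **theta1 window.** The dominant conformer has theta1 in (-30, 0]
  (open below, closed above; no reference value sits on a boundary). The
  minor conformer — amide carbonyl anti to the methoxy group — is flagged
  from tauOMe (outside the +30..+80 rotamer window and |tauOMe| >= 120)
  rather than from a separate eighth torsion; on the reference table this
  reproduces the five known anti records exactly. Everything else,
  including a handful of irregular theta1 values near -31..-41 degrees that
  the survey leaves unclassified, is `"other"`.
* **CF3 stagger.** `cf3_staggered` is |tauF| >= 150: one fluorine
  antiperiplanar to the carbonyl.
* **Z/E forms.** Z means the higher-priority N-substituent is sp to the
  carbonyl oxygen. Within H < methyl < primary < secondary < tertiary alkyl
  the order is by heavy-neighbor count of the alpha carbon; special classes
  (aryl, heteroatom alpha atoms such as the benzotriazole nitrogen or the
  sulfonyl sulfur) compare by the alpha atom's atomic number, and anything
  unresolvable is reported `"indeterminate"`, never guessed. The survey's
  13:4 Z:E ratio applies to tertiary amides derived from secondary amines;
  the report therefore presents that panel restricted to secondary-amine
  records (the remaining tertiary records carry special substituent classes)
  alongside the full per-arity tally.
* **Mosher type.** A secondary amide whose sp substituent is a secondary
  alkyl — the classical substrate of the NMR method. The methine statistics
  (tauH) are restricted to these records.

## Survey statistics

Two descriptors (tauF, tauAp) cluster around +/-180 and straddle the seam of
the angle convention. They are branch-shifted before averaging: every
positive value v becomes v - 360, giving a contiguous branch on (-360, 0],
and results re-wrap into (-180, +180] for reporting. Plain arithmetic means
and medians on the shifted branch are used instead of von Mises estimators:
the data cluster tightly, the branch shift removes the seam, and ordinary
statistics stay auditable against the printed table. Medians over an even
count take the midpoint of the central pair.

Windowed means use the survey's windows — theta1 in (-30, 0], theta2 in
[0, +50], tauOMe in [+30, +80] — with every excluded record listed by row
id, so the exclusion bookkeeping is part of the report, not a side effect.
Histograms use 10-degree bins, left-open/right-closed and aligned to zero
(0 falls in (-10, 0]). Nullable descriptors are dropped from their own
statistics with the count recorded; nothing is imputed.

One reference record (the sulfonamide-derived amide) stores the S-N-C1-O1
angle in the C1' column. Whether it belonged in the amide-planarity
statistics is not stated in the source survey; it is included by default
(`include_special_sp = TRUE`), which reproduces the printed +0.8 median,
and the toggle documents the effect (the median moves to +0.5 when it is
dropped, the rounded mean stays +2).

The printed panel rounds the way the survey prints: medians to one decimal
where the source prints one (theta1, tauSp), otherwise to the nearest
degree; full precision is always retained alongside.

## Perception choices

Bonds are perceived by covalent radii (Cordero-style values) with a 0.40
angstrom tolerance, hydrogen bonds to heavy atoms capped at 1.3 angstrom,
and interatomic distances below 0.5 angstrom treated as errors. Moiety
matching requires the exact MTPA-amide substructure (quaternary C2 with CF3,
methoxy, amide and phenyl arms); each match is one record, so bis- and
tetrakis-amides contribute several records per structure, as do multiple
conformers in one asymmetric unit. Only asymmetric-unit atoms are used: all
known MTPA-amide records are intra-asymmetric-unit, and documenting that
limitation beats silently reconstructing wrong molecules from symmetry
operators.

The sp/ap lateralization boundary is |torsion| = 90 inclusive for sp, with a
warning logged within 10 degrees of the boundary. For heavy-atom-only
models, a methine hydrogen on an sp3 alpha carbon with exactly three heavy
neighbors is inferred at 1.09 angstrom along the negated sum of the
neighbor unit vectors and flagged `h1p_inferred`, keeping the provenance of
tauH visible; aromatic alpha carbons never receive an inferred H.

Deterministic tie-breaks: two fluorines tying in |torsion| within 0.01
degrees resolve by atom label order; two ortho carbons tying exactly at 90
degrees resolve to the positive torsion. Both log a message.

## The synthetic generator

`build_mtpa_amide()` places atoms sequentially by bond length, bond angle
and torsion from three predecessors, so every supported torsion target is
met exactly (to floating point) before noise — construction order, not
post-hoc optimization, which makes the generator a closed-form oracle for
the pipeline. Standard internal coordinates are used (C-C 1.53, C=O 1.23,
amide C-N 1.35, C-F 1.34, C-O 1.43, aromatic C-C 1.39 angstrom; tetrahedral
109.5, trigonal 120 degrees). The CF3 torsion rotates the whole group with
the other two fluorines at +/-120 degrees; S chirality mirrors the R build;
the molecule is centered in a 20 angstrom orthorhombic P1 box.

Five amine templates cover the survey's moiety classes: isopropylamine
(Mosher type; all seven targets), n-propylamine (primary alkyl; no unique
methine H), 2-methylpyrrolidine (cyclic secondary amine; the ring constrains
tauAp and tauH, and the methyl makes the sp side a secondary alkyl so the
template realizes the cyclic-amine Z form — an unsubstituted pyrrolidine
would compare primary vs primary and be indeterminate), N-methyl-
isopropylamine (the E-prone tertiary motif) and a tetrakis-aryl template
(four anilide arms on a tetraphedral tetraphenylmethane-like scaffold,
standing in for the porphyrin-based tetrakis amides). For secondary-amide
templates the tauAp target orients the N-H hydrogen; the measured tauAp is
still null because R^ap is hydrogen. Free rotors that are not descriptor
targets (e.g. the N-isopropyl orientation in the tertiary template) are
chosen deterministically to maximize clearance from already-placed atoms.

`perturb_structure()` adds isotropic Gaussian noise; `noise_sigma` is the
root-mean-square displacement per atom (each Cartesian component gets sd
sigma/sqrt(3)), matching how isotropic displacement magnitudes are quoted
crystallographically. First-order error propagation then gives a per-torsion
standard deviation near 1.4 degrees at sigma = 0.02 angstrom, so about 95%
of recovered torsions land within 3 degrees of their targets — the
calibration the validation suite asserts over 200 perturbed builds. The
generator emulates idealized single-molecule geometries: it does not model
crystal packing, libration, disorder, riding-hydrogen constraints or
correlated least-squares errors, so passing recovery tests demonstrates the
measurement pipeline, not the behavior of real refinement noise.

`sample_survey()` draws torsion targets from wrapped normal distributions
centered on the survey's consensus conformation (theta1 -13, tauF -174,
tauSp +2, tauAp -174, tauH -11, theta2 +21, tauOMe +54 degrees; spreads 8,
4, 4, 4, 25, 12, 8 degrees — the methine spread reflects the broad
-60..+50 range of the observed methine angles, the others the spread of the
printed columns). Chirality is Bernoulli(1/2) unless forced.

## Validation problem sizes

The shipped suite checks: the full reference-table panel (58 records); the
torsion oracle on 1000 random quadruples (1e-9 degrees); the mirror theorem
on 200 generated structures across all five templates; exact (<= 0.5 degree)
recovery of all supported targets per template; 3-degree recovery over 200
perturbed builds at sigma 0.02; and parameter recovery of a 50-structure
sampled survey to within three standard errors. The whole suite runs in
about half a minute on one CPU.

## Known limitations

* Core CIF 1.1 only (cell parameters + fractional `_atom_site` loop);
  mmCIF/PDBx, disorder assemblies and symmetry-operator expansion are out of
  scope.
* Substituent classification is local (alpha atom and its first sphere);
  it is exactly what the Z/E bookkeeping needs, not a general CIP engine.
* The reference table stores printed values; standard uncertainties are
  carried but not propagated into the survey statistics, mirroring the
  source survey.
* Aromatic perception is six-membered carbocycle detection, sufficient for
  the phenyl/anilide chemistry of this family.
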