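# pulmolobe

Fully automatic lung **lobe segmentation** for paired inspiratory/expiratory
chest CT, with the validation statistics and the lobar **air-trapping**
quantification that go with it.

Regional (lobe-based) analysis of air trapping — an early marker of
small-airways disease in conditions such as cystic fibrosis — requires lobe
masks on both the inspiratory and the expiratory scan. Manual lobe
delineation on volumetric CT takes on the order of 90 minutes per subject;
expiratory scans are particularly hard to segment because parenchymal
density approaches soft tissue. `pulmolobe` implements the classical
airway-first pipeline for this problem:

1. airway tree segmentation by self-adapting iterative region growing
   (threshold escalation with a volume-explosion leak guard);
2. topology-preserving 3-D thinning and conversion of the skeleton into a
   rooted acyclic graph;
3. rule-based lobar labeling of the bronchi (RUL, RML, RLL, LUL, lingula,
   LLL);
4. left/right lung masks and threshold-based vessel segmentation with
   iterative lobar assignment of 3-D vessel objects (erode-and-split for
   ambiguous objects);
5. bronchial convex hulls and distance-based initial lobe masks;
6. Hessian-eigenvalue fissure enhancement (bright-plate filter
   (|λ1|−|λ2|)/(|λ1|+|λ2|), λ1 < 0) and a deterministic marker-based 3-D
   watershed that turns eroded initial masks plus fissure barriers into the
   final lobe map.

For validation the package provides Dice `D = 2|A∩M|/(|A|+|M|)`, Jaccard
`J = |A∩M|/|A∪M|`, pooled multi-region Dice, mean absolute (symmetric)
surface distance, Bland–Altman limits of agreement `mean(d) ± 1.96·sd(d)`,
and Pearson correlation. For quantification it computes lobar volumes and
the air-trapping index **E/I MLA** — the expiratory-to-inspiratory ratio of
the mean lung attenuation, computed per lobe on each phase's own mask
(values near 1 mean trapped air).

Because no clinical scans ship with the package, it includes a paired
inspiratory/expiratory **thorax phantom generator** with exact ground truth
(lobe map, lung masks, labeled airway centerlines, vessel and air-trap
masks, designed attenuations), on which every stage and statistic is
exercised.

## Worked example

```r
library(pulmolobe)

spec <- phantom_spec(seed = 7)           # 96x128x128, (1.5, 1, 1) mm
ph   <- generate_phantom(spec)           # insp + exp CT and ground truth

res  <- segment_lobes(ph$insp)           # the full pipeline, a few seconds
rep  <- validation_report(res$lobe_map, ph$truth$lobe_map)
print(rep)
```

```
<agreement_report> (six_lobe) pooled Dice 0.9490
 lobe   dice jaccard assd_mm volume_delta_cm3
  RUL 0.9708  0.9432  0.5299           1.2990
  RML 0.8158  0.6889  2.1351          -0.4425
  RLL 0.9516  0.9077  0.9071          -1.8660
  LUL 0.9504  0.9055  0.7225          -0.9255
  LLi 0.8978  0.8146  0.8754           1.0095
  LLL 0.9793  0.9594  0.3583          -0.7650
  volume Bland-Altman: mean -0.28 cm3, LoA [-2.66, 2.09]
```

Overlap with the ground truth is near-perfect for the fissure-bounded
lobes, the mean surface error is well under a voxel, and the weakest lobe
is the right middle lobe — the thin wedge between the two (incomplete)
right fissures, which is also the hardest lobe for clinical pipelines of
this design. Air trapping on the paired phases:

```r
tab <- lobe_quant_table(ph$insp, res$lobe_map, ph$exp,
                        segment_lobes(ph$exp)$lobe_map)
print(tab, digits = 3)
```

```
        lobe code mla_insp mla_exp ei_mla volume_insp_cm3 volume_exp_cm3
1        RUL    1     -724    -494  0.683            67.4           69.2
2        RML    2     -725    -491  0.677            27.0           27.5
3        RLL    3     -734    -553  0.753            86.3           84.1
4        LUL    4     -730    -499  0.684            38.4           39.4
5        LLi    5     -718    -494  0.689            18.0           18.5
6        LLL    6     -728    -570  0.783            91.6           90.3
7 whole_lung    0     -728    -530  0.728           328.7          329.2
```

The phantom plants trapped-air regions in the RLL and LLL; exactly those
lobes show E/I MLA pulled toward 1 (0.75 and 0.78 against ~0.68
elsewhere), and the whole-lung ratio (0.73) sits in the physiologic range
for spirometer-controlled pediatric expiration.

A command-line interface wrapping the same functions is installed at
`inst/cli/pulmolobe.R`:

```sh
Rscript inst/cli/pulmolobe.R phantom --seed 42 --out-dir ph/
Rscript inst/cli/pulmolobe.R segment --input ph/insp.nii.gz --output lobes.nii.gz --lobes 6
Rscript inst/cli/pulmolobe.R validate --auto lobes.nii.gz --ref ph/truth_lobes.nii.gz --report report.json
Rscript inst/cli/pulmolobe.R airtrap --insp ph/insp.nii.gz --insp-lobes li.nii.gz \
    --exp ph/exp.nii.gz --exp-lobes le.nii.gz --csv airtrap.csv
```

Volumes are read and written as NIfTI-1 (`.nii`, `.nii.gz`) or MetaImage
(`.mha`, `.mhd`); phase/kernel tags and the 5/6-lobe mode travel in a JSON
sidecar (`*.meta.json`).

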