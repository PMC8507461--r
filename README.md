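# irscatter

Computational occupational dosimetry for interventional radiology:
reconstruct the personal dose equivalent Hp(10) of staff from the X-ray
machine's irradiation-event log and a tracked operator position, using
Monte-Carlo photon transport of the scattered field — no physical
dosemeter required.

## The problem

Staff doses in interventional radiology are significant, spatially very
inhomogeneous and hard to measure: physical dosemeters have large energy,
rate and angular uncertainties at fluoroscopy energies, must be worn
correctly, and integrate over whole procedures. An alternative is to
*compute* the dose: modern angiography systems log every irradiation
event (tube voltage, filtration, C-arm angulation, field size, kerma-area
product P<sub>KA</sub>, reference-point air kerma K<sub>air</sub>,
timestamps) in a DICOM Radiation Dose Structured Report, and an indoor
positioning system can track where the operator stands. Combining the
two with a radiation-transport model yields a per-event, per-position
dose reconstruction.

## What the package computes

For each irradiation event:

1. **Source term** — a semi-empirical tungsten-anode spectrum
   Φ(E) ∝ (kVp − E)/E with K-characteristic lines, hardened by the
   inherent filtration and the logged Cu filtration
   (`generate_spectrum()`).
2. **Transport** — photons are sampled in the collimated beam for the
   logged C-arm angulation and field size, attenuated by the table, and
   transported analog through a patient phantom (a 10-bottle BOMAB-type
   segment set or a prism) with photoelectric absorption, Klein–Nishina
   Compton and Thomson-shaped coherent scattering. At every interaction a
   next-event (point-detector) estimate scores the scattered fluence
   spectrum at each point of interest, attenuated through phantom and
   optional ceiling shield (`run_event_simulation()`).
3. **Dose conversion** — the fluence spectrum is folded with ICRU-slab
   conversion coefficients, Hp(10)/Φ(E), and the relative result is made
   absolute with the machine-reported output of the event:
   Hp(10) = Hp(10)<sub>rel</sub> · P<sub>KA</sub> / P<sub>KA</sub><sup>sim</sup>
   (or the K<sub>air</sub> analogue), with a 10 % (k = 2) normalisation
   uncertainty plus the Monte-Carlo statistics (`normalize_event()`,
   `combine_uncertainty()`).
4. **Position** — the operator position is matched by timestamp and held
   fixed at the start of each event; long image acquisitions during which
   the operator walks away can be subdivided into frames that follow the
   trace, with the event output apportioned uniformly
   (`position_at_event_start()`, `subdivide_event()`).

`run_procedure()` orchestrates a whole procedure and reports per-point and
mean Hp(10) with expanded (k = 2) uncertainties, plus counts of simulated,
position-unknown and zero-output events. A synthetic-case generator
(`generate_case()`) emulates four reference scenarios (1–186 events,
54–1091 cm² fields, 66–86 kVp, 0.06–163 Gy·cm²) so the whole pipeline is
testable without clinical data.

## Worked example

```r
library(irscatter)

ev  <- irradiation_event("a0", t_start = 0, duration = 30, "fluoroscopy",
                         kvp = 79, filtration_cu = 0.3, field_area = 835,
                         p_ka = 4.1, k_air_ref = 17.6)
room <- room_model(phantom = bomab_phantom())          # C-arm defaults
pts  <- detector_points(data.frame(point_id = "chest",
                                   x = -0.7, y = 0, z = 0.3,
                                   label = "operator chest, 0.7 m"))
simulate_single_event(ev, room, pts, n_histories = 5e4, seed = 1)
#>   point_id hp10_uSv u_stat_uSv U_k2_uSv
#> 1    chest 9.787213   0.141733 1.018945
```

A 4.1 Gy·cm² fluoroscopy run at 79 kVp gives ≈ 9.8 µSv at the operator's
chest 0.7 m from the isocenter — about 2.4 µSv per Gy·cm², the expected
scale for unshielded scatter at that distance — with a k = 2 uncertainty
dominated by the 10 % output-normalisation term.

The same from the shell:

```sh
Rscript inst/cli/irscatter synth --case C --seed 3 --out-dir /tmp/caseC
Rscript inst/cli/irscatter run --events /tmp/caseC/events.csv \
    --trace /tmp/caseC/trace.csv --room /tmp/caseC/room.yaml \
    --points /tmp/caseC/points.csv --histories 20000 --seed 2 \
    --out /tmp/caseC/report.json
#> <irs_report>
#>     point_id           label  hp10_uSv   U_k2_uSv
#> 1      chest chest dosemeter 0.1331903 0.01373238
#> 2 shoulder_l   left shoulder 0.2130594 0.02168753
#> mean over points: 0.173 +/- 0.013 uSv (k=2)
#> events: 19 total, 19 simulated, 0 position-unknown, 0 zero-output
```

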