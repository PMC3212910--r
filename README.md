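# tissehr

A two-level (dual-model) implementation of **TISS**, Brazil's mandatory
standard for healthcare authorization and claim exchange between health
plans (payers) and providers. TISS prescribes paper forms and XML messages
but no underlying information model; `tissehr` re-designs it on the
openEHR-style archetype architecture, so the package is aimed at health
informatics researchers and engineers working on claims interoperability,
administrative EHR content, and archetype tooling.

The architecture separates two levels:

* a **reference model (RM)** — the fixed record structures
  (`COMPOSITION` → `SECTION` → `ENTRY` → `ITEM_TREE`/`ITEM_LIST`/
  `ITEM_TABLE`/`ITEM_SINGLE` → `ELEMENT`, with `CARE_ENTRY` subtypes
  `OBSERVATION`/`EVALUATION`/`INSTRUCTION`/`ACTION` and the administrative
  `ADMIN_ENTRY`), plus an **extended RM** in which `ADMIN_ENTRY` is
  specialized into `SUBMISSION` → `CLAIM` (`PROFESSIONAL_CLAIM`,
  `INSTITUTIONAL_CLAIM`), `AUTHORIZATION` and `ANNEX`, and the composition
  gains an `ISM_TRANSITION` carrying the claim status
  (`submitted | pending | denied | returned_for_correction | completed`);
* **archetypes** — constraint definitions over those classes, written in an
  ADL dialect (`ELEMENT[at0004] occurrences matches {0..1}`,
  `allow_archetype CLUSTER[at0015]` slots, `DV_TEXT matches {*}` leaves),
  combined by **templates** into the eleven TISS forms and flattened into
  operational templates for validation and form generation.

The package ships the three archetype fixture sets (ENTRY-rooted,
CLUSTER-rooted, extended-RM-rooted), an ADL parser/printer, a constraint
validator, lossless conversion between the plain and extended
representations, a seedable synthetic claim generator with single-violation
mutants, and a simulated provider↔payer EXTRACT exchange over REST-style
resources (`/organizationID/{resource_id}`, GET/POST/PUT/DELETE) with payer
adjudication and the claim lifecycle state machine.

## Worked example

```r
library(tissehr)

repo      <- tiss_repository(1)      # approach-1 archetypes, alias-aware
templates <- tiss_templates()        # the eleven TISS form templates

comp <- generate_composition(generator_config(seed = 42, "admission claim"),
                             repo, templates)
comp
#> COMPOSITION[at0000] <openEHR-EHR-COMPOSITION.tiss_claim.v1> -- admission claim
#>   content: 3 child node(s)

opt <- flatten(templates[["admission claim"]], repo)
validate_against_template(comp, opt, repo)
#> <validation report> valid, 0 finding(s)
```

The three content entries are the institutional claim header, the patient
evaluation and the performed services; validation walks the flattened
template and reports every violated constraint with its instance path (an
invalid claim yields findings such as
`OCCURRENCES_EXCEEDED at /data[at0001]/items[at0004]`, never an exception).

Converting to the extended reference model absorbs the repeated header
elements into class attributes and moves the status into the composition's
ISM transition:

```r
ext <- convert_base_to_extended(comp)
class(ext$content[[1]])[1]          #> "tiss_institutional_claim"
ext$content[[1]]$submission_id      #> "S-397482"
ext$content[[1]]$billing_date       #> "2011-10-22"
ext$ism_transition$current_state    #> "SUBMITTED"
```

The 11 populated header elements become 6 residual elements plus the RM
attributes, and `convert_extended_to_base(ext)` restores the original
composition exactly (`structural_equals` is `TRUE`).

The exchange simulation runs the full billing loop — the provider POSTs a
request extract, the payer adjudicates and responds:

```r
log <- run_roundtrip(generate_scenario(42, n_requests = 2),
                     policy_approve_all(), repo, templates)
r <- log$responses[[1]]$content[[1]]
r$authorization_id                   #> "AUTH-000001"
c(r$validity_start, r$validity_end)  #> "2011-11-01" "2011-12-01"
#> lifecycle: SUBMITTED -> COMPLETED
```

An approved authorization request receives an authorization id and a
30-day validity period; denial leads to `DENIED`, from which resubmission
(`run_roundtrip(..., resubmit = TRUE)`) is the only legal continuation.

A thin command-line wrapper lives at `inst/cli/tissehr-cli.R`
(`fixtures`, `templates`, `parse`, `validate`, `flatten`, `gen`,
`exchange`, `lifecycle` subcommands; exit 0 ok / 1 invalid / 2 usage /
3 I/O).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end behaviour from scratch: it builds all
three archetype sets and re-parses every emitted file, parses the bundled
institutional-claim reference listings and token-compares them with the
builder's output, generates and validates synthetic claims for all eleven
form templates, round-trips a claim through the extended reference model,
and re-runs the seeded exchange simulation twice to confirm byte
reproducibility, then writes the JSON report to `--out`.
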