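# foodont

Ontology-based food intolerance scoring and allergy rule inference.

## The problem

Food packaging rarely names ingredients the way consumers know them: ascorbic
acid may appear as "E300", "Vitamin C", "L-Ascorbic Acid" or "Ascorbate".
A consumer who must avoid a compound therefore cannot rely on string
comparison between their intolerance list and an ingredient list. `foodont`
is aimed at builders of dietary decision-support tools (shopping assistants,
kiosk apps, allergen screeners): it matches the two lists *through a food
ontology*, so equivalent, broader and narrower forms of a concept are
recognized and scored, and returns an intolerance score, an integer
percentage and a red/yellow/green verdict for each product.

## The model

Matching runs in two stages.

**Stage 1 — semantic enhancement.** Each raw intolerance term is expanded
through the ontology into the enhanced consumer list *C*: its full synonym
closure plus one hop of `hasGroup` (and optionally is-a) links.

**Stage 2 — concept matching.** Every consumer concept *C\_i* is classified
against product ingredient concepts *P\_j* into one of four degrees of match

| relation | meaning | degree |
|---|---|---|
| Exact | identical or synonym-equivalent | 1 |
| Plugin | one strictly subsumes the other (see `direction` option) | 0.75 |
| Subsume | the converse, or siblings under a common ancestor | 0.5 |
| Dissimilar | no hierarchy connection | 0 |

Hierarchy links are weighted: a parent with *n* direct subconcepts gives each
child edge weight 1/*n* (developer overrides win), and a chain multiplies its
edge weights, `d_weight(A,Z) = d_weight(A,B) * ... * d_weight(Y,Z)`. A greedy
sequential pass matches each *C\_i* to its maximum-degree remaining partner;
each matched pair contributes

```
MatchingScore(C_i, P_j) * d_weight(C_i, P_j) / |distance(C_i, P_j)|
```

The aggregate uses a modified Jaro–Winkler factor over the concept lists,
with `m` the sum of matched degrees, `l` the number of non-Dissimilar pairs
and `k = 0.1`:

```
d_j = (m/n_C + m/n_P) / 2
d_w = d_j + l * k * (1 - d_j)
IntoleranceScore(C, P) = sum(pair terms) / ((n_C / n_P) * d_w)
percentage = floor(score * 100 / max(n_C, n_P))
```

The verdict is RED when any pair is Exact, YELLOW when only Plugin/Subsume
pairs exist, GREEN otherwise. Independently, a DL-safe forward-chaining
engine applies SWRL-style allergy rules
(`Consumer(?c), Has_Allergy(?c, Lactose_Allergy), ... ->
HAS_LACTOSE_RISK(?c, Aluminium_Silicate)`), with ontology-backed expansion so
that synonyms (Kaolin) and subclasses (E554–E556) of an allergen also fire
its rule.

## Worked example

```r
library(foodont)
wx  <- worked_example()            # ontology + consumer + two products
res <- evaluate_product(wx$ontology, wx$consumer, wx$products$P2)
res
#> <match_result> 8690000000024: score 1.7003, 56%, verdict RED
#>   m = 2.250, l = 3, d_j = 0.7500, d_w = 0.8250 (n_C = 3, n_P = 3)
#>            c_concept          p_concept relation       term
#> 1 d-isoascorbic acid ascorbyl palmitate  Subsume 0.02777778
#> 2              algin    sodium alginate   Plugin 0.37500000
#> 3         vitamin b3             niacin    Exact 1.00000000
```

The consumer is intolerant to D-Isoascorbic Acid, Algin and Vitamin B3. In
product 2, D-Isoascorbic Acid relates to Ascorbyl Palmitate as a sibling
under Ascorbic Acid (two 1/3-weighted links at distance 2, term 0.0278),
Algin is a direct parent of Sodium Alginate (Plugin, weight 1/2, term
0.375), and Vitamin B3 is an exact synonym of Niacin (term 1). With
`m = 2.25` matched degree over two lists of three, `d_j = 0.75`,
`d_w = 0.825`, the score is 1.70: 56% of this product's matchable content is
problematic, and the Exact niacin pair makes the verdict RED. Product 1 of
the same fixture scores 1.015 → 33%, YELLOW.

A command-line wrapper ships in `inst/cli/foodont`:

```sh
Rscript inst/cli/foodont fixtures --out demo
Rscript inst/cli/foodont score --ontology demo/worked_ontology.yaml \
    --consumer demo/consumer.yaml --product demo/product_p2.yaml
```

(exit status 2 flags a RED verdict for scripting).

## Package layout

- `R/ontology.R` — ontology graph, edge/path weights, hierarchy queries
- `R/enhance.R` — stage-1 semantic enhancement
- `R/cme.R` — relation classification, greedy matching, Jaro–Winkler, score
- `R/rules.R` — rule parser, forward chaining, concept expansion
- `R/report.R` — verdict, profile bands, reports
- `R/fixtures.R` — worked example, seeded synthetic generator, match oracle
- `R/io.R` — OWL/XML-subset and YAML fixture readers/writers
- `vignettes/concept-matching.Rmd` — methods and design notes
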