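# DrugBank-like XML dialect

`parse_drugbank_xml()` reads a deliberately minimal dialect modelled on the
public DrugBank schema. It is exercised only on bundled fixture files;
full-schema robustness is out of scope. `synthetic_drugbank.xml` is an
annotated synthetic example.

A document is a `<drugbank>` element containing `<drug>` elements. Within a
drug:

| element | meaning |
|---|---|
| `drugbank-id` | drug entity id (required) |
| `name` | drug name text (required; every entity needs a name) |
| `description`, `indication`, `pharmacodynamics`, `mechanism-of-action`, `metabolism` | optional single text fields |
| `synonyms/synonym` | repeated synonym items, source order preserved |
| `categories/category` | `category` (name) + `mesh-id` → `category` triple to a MeSH entity |
| `atc-codes/atc-code[@code]` | `atc` triples to the leaf code *and every ancestor level*; hierarchy edges (`atc_hypernym`) are derived |
| `pathways/pathway` | `smpdb-id`, optional `name`/`description` → `pathway` triple |
| `drug-interactions/drug-interaction` | `drugbank-id` (+`name`) of the partner → `interact` triple (closed symmetrically) |
| `targets|enzymes|carriers|transporters//polypeptide[@id]` | UniProt-style protein with optional `name`, `general-function` (→ description), `gene-name`, `synonyms` → `target`/`enzyme`/`carrier`/`transporter` triple |

Unknown child elements of `<drug>` produce a warning and are skipped.
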