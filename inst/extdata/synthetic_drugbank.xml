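<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic fixture in the minimal DrugBank-like dialect documented in
     README-drugbank-dialect.md. Identifiers follow public nomenclature
     (DrugBank/MeSH/ATC/UniProt-style); all free text is written for this
     fixture. -->
<drugbank>
  <drug>
    <drugbank-id>DB00295</drugbank-id>
    <name>Morphine</name>
    <description>An opioid analgesic alkaloid used for the relief of moderate to severe pain.</description>
    <indication>Management of severe acute and chronic pain.</indication>
    <pharmacodynamics>Produces analgesia, euphoria and sedation through opioid receptor agonism.</pharmacodynamics>
    <mechanism-of-action>Agonist at the mu-opioid receptor in the central nervous system.</mechanism-of-action>
    <metabolism>Primarily hepatic glucuronidation.</metabolism>
    <synonyms>
      <synonym>Morphia</synonym>
      <synonym>Morphinum</synonym>
    </synonyms>
    <categories>
      <category>
        <category>Alkaloids</category>
        <mesh-id>D000470</mesh-id>
      </category>
      <category>
        <category>Anesthetics</category>
        <mesh-id>D018681</mesh-id>
      </category>
    </categories>
    <atc-codes>
      <atc-code code="A07DA52"/>
      <atc-code code="N02AA51"/>
      <atc-code code="N02AA01"/>
      <atc-code code="N02AG01"/>
    </atc-codes>
    <pathways>
      <pathway>
        <smpdb-id>SMP0000680</smpdb-id>
        <name>Morphine Action Pathway</name>
        <description>Signalling cascade of opioid receptor activation.</description>
      </pathway>
    </pathways>
    <drug-interactions>
      <drug-interaction>
        <drugbank-id>DB00813</drugbank-id>
        <name>Fentanyl</name>
      </drug-interaction>
    </drug-interactions>
    <targets>
      <target>
        <polypeptide id="P35372">
          <name>Mu-type opioid receptor</name>
          <general-function>G-protein coupled opioid receptor activity.</general-function>
          <gene-name>OPRM1</gene-name>
          <synonyms>
            <synonym>MOR-1</synonym>
          </synonyms>
        </polypeptide>
      </target>
    </targets>
    <enzymes>
      <enzyme>
        <polypeptide id="P08684">
          <name>Cytochrome P450 3A4</name>
          <general-function>Monooxygenase involved in drug metabolism.</general-function>
          <gene-name>CYP3A4</gene-name>
        </polypeptide>
      </enzyme>
    </enzymes>
  </drug>
  <drug>
    <drugbank-id>DB00813</drugbank-id>
    <name>Fentanyl</name>
    <indication>Breakthrough pain management.</indication>
    <synonyms>
      <synonym>Fentanil</synonym>
    </synonyms>
    <atc-codes>
      <atc-code code="N02AB03"/>
    </atc-codes>
    <drug-interactions>
      <drug-interaction>
        <drugbank-id>DB00295</drugbank-id>
        <name>Morphine</name>
      </drug-interaction>
    </drug-interactions>
    <transporters>
      <transporter>
        <polypeptide id="P08183">
          <name>P-glycoprotein 1</name>
          <gene-name>ABCB1</gene-name>
        </polypeptide>
      </transporter>
    </transporters>
  </drug>
</drugbank>
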