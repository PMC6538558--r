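<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">
  <xs:element name="codaml">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="ku" type="kuType" minOccurs="0" maxOccurs="unbounded"/>
      </xs:sequence>
      <xs:attribute name="formatVersion" type="xs:string" use="required"/>
      <xs:attribute name="creationDate" type="xs:string"/>
    </xs:complexType>
  </xs:element>
  <xs:complexType name="kuType">
    <xs:sequence>
      <xs:element name="subject" type="entityHolderType"/>
      <xs:element name="predicate" type="xs:string"/>
      <xs:element name="predicateInReference" type="xs:string" minOccurs="0"/>
      <xs:element name="object" type="entityHolderType"/>
      <xs:element name="environmentalContext" type="environmentalContextType"
                  minOccurs="0" maxOccurs="unbounded"/>
      <xs:element name="species" type="xs:string"/>
      <xs:element name="reference" type="referenceType" maxOccurs="unbounded"/>
      <xs:element name="evidenceScore" type="evidenceScoreType" minOccurs="0"/>
    </xs:sequence>
  </xs:complexType>
  <xs:complexType name="entityHolderType">
    <xs:sequence>
      <xs:element name="entity" type="entityType"/>
    </xs:sequence>
  </xs:complexType>
  <xs:complexType name="entityType">
    <xs:sequence>
      <xs:element name="entityCore" type="entityCoreType" maxOccurs="unbounded"/>
      <xs:element name="anatomicalContext" type="anatomicalContextType" minOccurs="0"/>
    </xs:sequence>
  </xs:complexType>
  <xs:complexType name="entityCoreType">
    <xs:sequence>
      <xs:element name="id" type="xs:string"/>
      <xs:element name="coreType" type="xs:string"/>
      <xs:element name="moleculeType" type="xs:string" minOccurs="0"/>
      <xs:element name="isoform" type="xs:string" minOccurs="0"/>
      <xs:element name="modification" type="xs:string" minOccurs="0" maxOccurs="unbounded"/>
    </xs:sequence>
  </xs:complexType>
  <xs:complexType name="anatomicalContextType">
    <xs:sequence>
      <xs:element name="organ" type="xs:string" minOccurs="0"/>
      <xs:element name="tissue" type="xs:string" minOccurs="0"/>
      <xs:element name="cell" type="xs:string" minOccurs="0"/>
    </xs:sequence>
  </xs:complexType>
  <xs:complexType name="environmentalContextType">
    <xs:sequence>
      <xs:element name="contextType" type="xs:string"/>
      <xs:element name="contextId" type="xs:string"/>
    </xs:sequence>
  </xs:complexType>
  <xs:complexType name="referenceType">
    <xs:sequence>
      <xs:element name="referenceType" type="xs:string"/>
      <xs:element name="name" type="xs:string"/>
      <xs:element name="description" type="xs:string" minOccurs="0"/>
      <xs:element name="recordId" type="xs:string" minOccurs="0"/>
      <xs:element name="version" type="xs:string" minOccurs="0"/>
      <xs:element name="acquisitionDate" type="xs:string" minOccurs="0"/>
    </xs:sequence>
  </xs:complexType>
  <xs:complexType name="evidenceScoreType">
    <xs:simpleContent>
      <xs:extension base="xs:string">
        <xs:attribute name="type" type="xs:string" use="required"/>
      </xs:extension>
    </xs:simpleContent>
  </xs:complexType>
</xs:schema>
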