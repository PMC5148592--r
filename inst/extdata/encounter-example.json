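{"record_id":"encounter-0001","ehr_id":"ehr-0001","version":1,"active":true,"created_at":"2023-05-01T09:30:00Z","updated_at":"2023-05-01T09:30:00Z","structure_id":null,"archetype_class":"openEHR-EHR-COMPOSITION.encounter.v1.lbl-00001","path_from_parent":"","content[at0001]":[{"archetype_class":"openEHR-EHR-SECTION.vital_signs.v1","path_from_parent":"/content[at0001]","content[at0001]":[{"archetype_class":"openEHR-EHR-SECTION.physical_exam.v1","path_from_parent":"/content[at0001]","content[at0001]":[{"archetype_class":"openEHR-EHR-ADMIN_ENTRY.admission.v1","path_from_parent":"/content[at0001]","content[at0001]":[{"archetype_class":"openEHR-EHR-SECTION.history.v1","path_from_parent":"/content[at0001]","content[at0001]":[{"archetype_class":"openEHR-EHR-EVALUATION.problem_list.v1","path_from_parent":"/content[at0001]","content[at0001]":[{"archetype_class":"openEHR-EHR-OBSERVATION.blood_pressure.v1","path_from_parent":"/content[at0001]","data":{"events[at0006]":[{"value":{"magnitude":142.5,"units":"mm[Hg]"}}]}}]}]}]}]}]}],"context":{"start_time":"2023-05-01T09:30:00Z"}}
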